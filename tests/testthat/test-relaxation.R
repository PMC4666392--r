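numeric_gradient <- function(net, xyz, h = 1e-6) {
  g <- matrix(0, nrow(xyz), 3)
  for (i in seq_len(nrow(xyz))) {
    for (d in 1:3) {
      xp <- xyz; xp[i, d] <- xp[i, d] + h
      xm <- xyz; xm[i, d] <- xm[i, d] - h
      g[i, d] <- (network_energy(net, xp) - network_energy(net, xm)) / (2 * h)
    }
  }
  g
}

test_that("analytic gradient matches numeric differentiation", {
  set.seed(301)
  for (k in 1:50) {
    s <- build_filament_strand("TTTTTT")
    s <- perturb_structure(s, sigma = 0.6)
    anch <- tibble::tibble(node = c(1L, 7L), k = 0.5,
                           tx = rnorm(2), ty = rnorm(2), tz = rnorm(2))
    net <- build_network(s, anchors = anch)
    xyz <- coords_of(s)
    ga <- network_gradient(net, xyz)
    gn <- numeric_gradient(net, xyz)
    rel <- max(abs(ga - gn)) / max(1, max(abs(ga)))
    expect_lt(rel, 1e-4)
  }
})

test_that("built structures are at rest in their own network", {
  s <- build_filament_strand(strrep("T", 9))
  net <- build_network(s)
  expect_lt(network_energy(net), 1e-9)
  d <- build_bdna("ACGTACGTA")
  expect_lt(network_energy(build_network(d)), 1e-6)
})

test_that("minimization decreases energy monotonically and converges", {
  s <- perturb_structure(build_filament_strand(strrep("T", 9)), 0.4, seed = 5)
  net <- build_network(s)
  res <- minimize(net, snapshot_every = 10)
  expect_true(res$converged)
  expect_true(all(diff(res$trace$energy) <= 1e-12))
  expect_lte(res$trace$gnorm[nrow(res$trace)], fil_defaults()$minim_tol)
  expect_gt(length(res$snapshots), 0)
  expect_error(minimize(net, tol = 0), "> 0")
})

test_that("anchored atoms end near their targets", {
  s <- build_filament_strand("TTTTTT")
  xyz <- coords_of(s)
  k_anchor <- 2
  tgt <- xyz[1, ] + c(0.5, 0, 0)
  anch <- tibble::tibble(node = 1L, k = k_anchor,
                         tx = tgt[1], ty = tgt[2], tz = tgt[3])
  net <- build_network(s, anchors = anch)
  res <- minimize(net)
  dev <- vlen(coords_of(res$structure)[1, ] - tgt)
  expect_lte(dev, sqrt(res$energy / k_anchor) + 1e-6)
})

test_that("wide junction gaps are strand breaks, not bonds", {
  m <- default_model()
  net <- build_network(m)
  # no O3'-P bond should be longer than the break budget at build time
  xyz <- coords_of(m)
  b <- net$bonds
  at <- net$atoms$atom
  o3p <- at[b$i] == "O3'" & at[b$j] == "P"
  d <- sqrt(rowSums((xyz[b$i[o3p], , drop = FALSE] -
                       xyz[b$j[o3p], , drop = FALSE])^2))
  expect_true(all(d < 5))
  # the outgoing chain is interrupted at the tail junctions: fewer O3'-P
  # bonds than an unbroken chain would have
  res_o <- sort(unique(m$residue_index[m$chain == "O"]))
  ch_o <- net$atoms$chain[b$i[o3p]]
  expect_lt(sum(ch_o == "O"), length(res_o) - 1L)
})

test_that("backbone closure restores O3'-P bonds without moving phosphates", {
  frag <- build_filament_strand("TTT")
  sc <- filament_screw()
  frags <- lapply(0:3, function(k) apply_screw(sc, frag, k))
  res <- close_backbone(frags, sc)
  expect_true(res$converged)
  s <- res$structure
  for (ri in res$junction_res) {
    gap <- vlen(apos(s, "A", ri, "O3'") - apos(s, "A", ri + 1, "P"))
    expect_equal(gap, 1.6, tolerance = 0.2)
  }
  # anchored phosphates stay put (drift < 0.5 A)
  p_new <- s[s$atom == "P", ]
  p_new <- as.matrix(p_new[order(p_new$residue_index), c("x", "y", "z")])
  p_old <- do.call(rbind, lapply(frags, function(f) {
    a <- f[f$atom == "P", ]
    as.matrix(a[order(a$residue_index), c("x", "y", "z")])
  }))
  expect_lt(max(sqrt(rowSums((p_new - p_old)^2))), 0.5)
  # an impossible gap is refused with the offending residue named
  far <- transform_structure(frag, diag(3), c(50, 0, 0))
  expect_error(close_backbone(list(frag, far), sc), "residue 3")
})

test_that("radial pull moves selected phosphates and preserves the screw", {
  s <- build_filament_strand(strrep("T", 9),
                             params = filament_params(radius = 12))
  res <- radial_pull(s, c(1, 2, 4, 5, 7, 8), 15)
  ps <- res$structure
  r <- strand_radius(ps)
  pulled <- r$radius[r$residue_index %in% c(1, 2, 4, 5, 7, 8)]
  expect_true(all(abs(pulled - 15) < 0.2))
  fit_window <- function(x) {
    a <- x[x$residue_index %in% 1:6, ]
    a <- a[order(a$residue_index, a$atom), ]
    fit_screw(as.matrix(a[a$residue_index <= 3, c("x", "y", "z")]),
              as.matrix(a[a$residue_index >= 4, c("x", "y", "z")]))
  }
  f0 <- fit_window(s)
  f1 <- fit_window(ps)
  expect_lt(abs(f1$angle_per_step - f0$angle_per_step) / f0$angle_per_step, 0.01)
  expect_lt(abs(f1$translation_per_step - f0$translation_per_step) /
              f0$translation_per_step, 0.01)
  expect_error(radial_pull(s, c(1, 2), 0), "> 0")
  expect_error(radial_pull(s, 99, 15), "selection matches no residues")
})
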