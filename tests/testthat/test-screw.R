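test_that("screw fitting recovers forward-constructed transforms (oracle)", {
  set.seed(101)
  for (k in 1:50) {
    axis_dir <- rnorm(3); axis_dir <- axis_dir / vlen(axis_dir)
    tr <- screw_transform(axis_point = rnorm(3, sd = 10),
                          axis_dir = axis_dir,
                          angle_per_step = runif(1, 5, 175),
                          translation_per_step = runif(1, 0.5, 20))
    pts <- matrix(rnorm(30, sd = 8), 10, 3)
    moved <- apply_screw(tr, pts, 1)
    fit <- fit_screw(pts, moved)
    expect_lt(abs(fit$angle_per_step - tr$angle_per_step), 1e-6)
    expect_lt(abs(fit$translation_per_step - tr$translation_per_step), 1e-6)
    expect_lt(abs(abs(sum(fit$axis_dir * tr$axis_dir)) - 1), 1e-9)
    expect_lt(attr(fit, "rmsd"), 1e-6)
  }
})

test_that("pure translations and degenerate inputs are handled", {
  pts <- matrix(rnorm(30), 10, 3)
  moved <- sweep(pts, 2, -c(1, 2, 3))
  fit <- fit_screw(pts, moved)
  expect_equal(fit$angle_per_step, 0)
  expect_equal(fit$translation_per_step, vlen(c(1, 2, 3)), tolerance = 1e-9)

  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fit_screw(line, line), "collinear")
  expect_error(fit_screw(pts[1:2, ], moved[1:2, ]), "at least 3")
  expect_error(fit_screw(pts, moved[1:5, ]), "paired")
})

test_that("apply_screw is a rigid motion with an exact inverse", {
  s <- build_filament_strand("TTTTTT")
  tr <- filament_screw()
  s2 <- apply_screw(tr, s, 2)
  d0 <- as.matrix(dist(coords_of(s)))
  d2 <- as.matrix(dist(coords_of(s2)))
  expect_equal(d0, d2, tolerance = 1e-9)
  s0 <- apply_screw(tr, s2, -2)
  expect_equal(coords_of(s0), coords_of(s), tolerance = 1e-9)
})

test_that("replicate_along_screw renumbers copies sequentially", {
  frag <- build_filament_strand("TTT")
  strand <- replicate_along_screw(frag, filament_screw(), 6)
  expect_equal(sort(unique(strand$residue_index)), 1:18)
  # copy k equals fragment moved by k-1 steps
  third <- strand[strand$residue_index %in% 7:9, ]
  moved <- apply_screw(filament_screw(), frag, 2)
  expect_equal(coords_of(fil_structure(third)), coords_of(moved),
               tolerance = 1e-9)
  expect_error(replicate_along_screw(frag, filament_screw(), 0), ">= 1")
})

test_that("infer_axis recovers the construction axis", {
  s <- build_filament_strand(strrep("T", 18))
  ax <- infer_axis(s, period = 3)
  expect_equal(abs(sum(ax$direction * c(0, 0, 1))), 1, tolerance = 1e-9)
  expect_lt(vlen(ax$point[1:2]), 1e-6)
  short <- suppressWarnings(build_filament_strand("TTTTT"))
  expect_error(infer_axis(short, period = 3), "two periods")
})

test_that("consecutive base pairs of ideal B-DNA are related by 36 deg / 3.38 A", {
  d <- build_bdna("ACGTACGTA")
  a <- d[d$chain == "A" & d$residue_index %in% 1:3, ]
  b <- d[d$chain == "A" & d$residue_index %in% 2:4, ]
  fit <- fit_screw(as.matrix(a[order(a$residue_index, a$atom), c("x", "y", "z")]),
                   as.matrix(b[order(b$residue_index, b$atom), c("x", "y", "z")]))
  expect_equal(fit$angle_per_step, 36, tolerance = 1e-6)
  expect_equal(fit$translation_per_step, 3.38, tolerance = 1e-6)
})
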