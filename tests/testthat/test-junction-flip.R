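test_that("default tails meet the filament at the configured bend", {
  m <- default_model()
  expect_length(fil_meta(m)$junctions, 2)
  expect_equal(junction_angle(m, 1), 90, tolerance = 1e-6)
  expect_equal(junction_angle(m, 2), 90, tolerance = 1e-6)
})

test_that("build_junction realises arbitrary bends and validates chains", {
  fil <- build_filament_strand(strrep("T", 9), chain = "F")
  b <- build_bdna("ACGTAC")
  j <- build_junction(b, fil, 45)
  expect_equal(junction_angle(j), 45, tolerance = 1)
  # backbone continuity at the junction
  o3 <- apos(j, "F", 9, "O3'")
  p <- apos(j, "A", 1, "P")
  expect_equal(vlen(o3 - p), fil_defaults()$o3p_len, tolerance = 1e-6)
  expect_error(build_junction(build_bdna("ACGTAC", chains = c("F", "G")), fil, 45),
               "share chain")
})

test_that("junction tags survive rigid motion", {
  m <- default_model()
  set.seed(21)
  for (k in 1:5) {
    mo <- random_motion()
    m2 <- transform_structure(m, mo$R, mo$t)
    expect_equal(junction_angle(m2, 1), junction_angle(m, 1), tolerance = 1e-6)
    expect_equal(junction_angle(m2, 2), junction_angle(m, 2), tolerance = 1e-6)
  }
})

test_that("duplet flip pairs the 5' duplet and leaves everything else fixed", {
  m <- default_model()
  m2 <- flip_duplet(m, 2)
  bp <- basepair_metrics(m2)
  # levels 5 and 6 (the 5'-most duplet of triplet 2) become paired
  expect_equal(bp$state[bp$pair_index %in% c(5, 6)], c("paired", "paired"))
  # the triplet's 3' base (level 4) stays unflipped (L2-blocked)
  expect_equal(bp$state[bp$pair_index == 4], "unflipped")
  # the initiating and outgoing strands are unmoved
  for (ch in c("I", "O")) {
    expect_equal(coords_of(fil_structure(m2[m2$chain == ch, ])),
                 coords_of(fil_structure(m[m$chain == ch, ])))
  }
  # exactly two complementary residues change
  d <- rowSums(abs(coords_of(m2) - coords_of(m)))
  moved <- unique(paste(m$chain, m$residue_index)[d > 1e-9])
  expect_length(moved, 2)
  expect_true(all(startsWith(moved, "C ")))
  # flipped pairs sit at the pair span, backbone continuity preserved
  expect_equal(bp$D1[bp$pair_index %in% c(5, 6)], rep(10.4, 2),
               tolerance = 1e-6)
  sII <- fil_meta(m2)$site_II
  rc <- sII$comp_res[6]   # 5'-most flipped residue
  expect_equal(vlen(apos(m2, "C", rc, "O3'") - apos(m2, "C", rc + 1, "P")),
               fil_defaults()$o3p_len, tolerance = 1e-6)
})

test_that("duplet flip validates its arguments and state", {
  m <- default_model()
  expect_error(flip_duplet(m, 3), "1..2")
  expect_error(flip_duplet(m, 0), "1..2")
  expect_error(flip_duplet(m, 1, which = "3p-duplet"), "L2")
  m2 <- flip_duplet(m, 1)
  expect_error(flip_duplet(m2, 1), "already paired")
  expect_equal(fil_meta(m2)$flipped, 1L)
})

test_that("flip metrics D1/theta1 discriminate the states", {
  m <- default_model()
  bp0 <- basepair_metrics(m)
  expect_true(all(bp0$state == "unflipped"))
  post <- make_postsynaptic_reference(6)
  bpp <- basepair_metrics(post)
  expect_true(all(bpp$state == "paired"))
  expect_true(min(bp0$D1) > max(bpp$D1) + fil_defaults()$d1_tol)
})
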