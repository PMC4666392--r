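test_that("ideal B-DNA has canonical helical parameters", {
  d <- build_bdna("ACGTACGTA")
  sm <- step_summary(step_parameters(d, chain = "A"))
  expect_equal(sm$mean_rise, 3.38, tolerance = 1e-9)
  expect_equal(sm$mean_twist, 36, tolerance = 1e-9)
  r <- strand_radius(d, chain = "A")
  expect_equal(mean(r$radius), 9.4, tolerance = 1e-9)
  expect_equal(extension_factor(d, chain = "A"), 1.0, tolerance = 1e-9)
})

test_that("B-DNA pairs are antiparallel Watson-Crick at the pair span", {
  seqa <- "ACGTACGTA"
  d <- build_bdna(seqa)
  n <- nchar(seqa)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases_a <- strsplit(seqa, "")[[1]]
  for (i in seq_len(n)) {
    c1a <- apos(d, "A", i, "C1'")
    c1b <- apos(d, "B", n + 1 - i, "C1'")
    expect_equal(vlen(c1a - c1b), fil_defaults()$pair_span, tolerance = 1e-9)
    nm_b <- d$residue_name[d$chain == "B" & d$residue_index == n + 1 - i][1]
    expect_equal(nm_b, paste0("D", comp[[bases_a[i]]]))
  }
})

test_that("filament strands realise the triplet-patterned means exactly", {
  s <- build_filament_strand(strrep("T", 18))
  st <- step_parameters(s)
  sm <- step_summary(st)
  expect_equal(sm$mean_rise, 5.1, tolerance = 1e-9)
  expect_equal(sm$mean_twist, 20, tolerance = 1e-9)
  cfg <- fil_defaults()
  inter <- seq(3, 17, by = 3)
  expect_equal(st$axial_rise[inter], rep(cfg$inter_rise, length(inter)),
               tolerance = 1e-9)
  expect_equal(st$axial_rise[-inter], rep(cfg$intra_rise, 17 - length(inter)),
               tolerance = 1e-9)
  expect_equal(st$twist[inter], rep(cfg$inter_twist, length(inter)),
               tolerance = 1e-9)
  expect_equal(mean(strand_radius(s)$radius), cfg$r_initiating,
               tolerance = 1e-9)
})

test_that("intra-triplet phosphate spacing stays compact", {
  # contiguity: consecutive intra-triplet P-P distances stay below 8 A (the
  # inter-triplet rises are by definition larger: the stretching lives there)
  s <- build_filament_strand(strrep("T", 18))
  st <- step_parameters(s)
  intra <- setdiff(seq_len(17), seq(3, 17, by = 3))
  expect_true(all(st$pp_distance[intra] < 8))
  expect_true(all(st$pp_distance[seq(3, 17, by = 3)] >
                    max(st$pp_distance[intra])))
})

test_that("displaced strands are more extended: P-P ordering property", {
  m <- default_model()
  sII <- fil_meta(m)$site_II
  pp_out <- mean_pp_dist(m, "O", sort(sII$outgoing_res))
  pp_init <- mean_pp_dist(m, "I", sort(sII$init_res))
  expect_gt(pp_out, pp_init)
})

test_that("builders validate their inputs", {
  expect_error(build_bdna("ACGX"), "alphabet")
  expect_error(build_bdna(""), "non-empty|alphabet")
  expect_warning(build_filament_strand("TTTT"), "multiple of 3")
  expect_error(helical_params(3.6, 8.1, 25, 10, radius = 0), "> 0")
  expect_error(triplet_pattern(-1), ">= 0")
  expect_error(triplet_pattern(2, bend_angle = 180), "bend_angle")
})

test_that("synaptic builder validates pattern and sequence", {
  expect_error(build_synaptic_model(pattern = triplet_pattern(0, 0, 0)),
               "degenerate")
  expect_error(build_synaptic_model(pattern = triplet_pattern(0, 6, 6)),
               "at least one")
  expect_error(build_synaptic_model("ACGT"), "too short")
  expect_warning(build_synaptic_model(pattern = triplet_pattern(6, 0, 0)),
                 "outside the studied range")
})

test_that("the default synaptic model places strands at their radii", {
  m <- default_model()
  sII <- fil_meta(m)$site_II
  cfg <- fil_defaults()
  expect_equal(mean(strand_radius(m, "I", residues = sort(sII$init_res))$radius),
               cfg$r_initiating, tolerance = 1e-9)
  expect_equal(mean(strand_radius(m, "C", residues = sort(sII$comp_res))$radius),
               cfg$r_complementary, tolerance = 1e-9)
  expect_equal(mean(strand_radius(m, "O", residues = sort(sII$outgoing_res))$radius),
               cfg$r_outgoing, tolerance = 1e-9)
  # all three strands carry the filament pattern
  for (ch in c("I", "C", "O")) {
    res <- switch(ch, I = sII$init_res, C = sort(sII$comp_res),
                  O = sort(sII$outgoing_res))
    sm <- step_summary(step_parameters(m, chain = ch, residues = res))
    expect_equal(sm$mean_rise, 5.1, tolerance = 1e-9)
    expect_equal(sm$mean_twist, 20, tolerance = 1e-6)
  }
})
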