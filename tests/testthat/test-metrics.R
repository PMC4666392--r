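test_that("step_parameters reports per-step rise, twist and spacing", {
  s <- build_filament_strand(strrep("T", 9))
  st <- step_parameters(s)
  expect_s3_class(st, "fil_steps")
  expect_equal(nrow(st), 8)
  expect_named(st, c("step_index", "axial_rise", "twist", "pp_distance"))
  # P-P distance is the chord: never smaller than the axial rise
  expect_true(all(st$pp_distance >= st$axial_rise))
  sm <- step_summary(st)
  expect_equal(sm$n_steps, 6)   # whole triplets only
})

test_that("step_parameters validates residue ranges", {
  s <- build_filament_strand(strrep("T", 9))
  expect_error(step_parameters(s, residues = c(1, 99)),
               "missing P atom in residue 99")
  expect_error(step_parameters(s, residues = 1), "fewer than 2")
  m <- default_model()
  expect_error(step_parameters(m), "single chain")
})

test_that("metrics are invariant under rigid motion", {
  m <- default_model()
  sII <- fil_meta(m)$site_II
  sm0 <- step_summary(step_parameters(m, "I", residues = sII$init_res))
  r0 <- strand_radius(m, "O", residues = sort(sII$outgoing_res))$radius
  bp0 <- basepair_metrics(m)
  j0 <- junction_angle(m, 1)
  reg0 <- registration_check(m)
  set.seed(401)
  for (k in 1:20) {
    mo <- random_motion()
    m2 <- transform_structure(m, mo$R, mo$t)
    sm <- step_summary(step_parameters(m2, "I", residues = sII$init_res))
    expect_equal(sm$mean_rise, sm0$mean_rise, tolerance = 1e-6)
    expect_equal(sm$mean_twist, sm0$mean_twist, tolerance = 1e-6)
    expect_equal(strand_radius(m2, "O", residues = sort(sII$outgoing_res))$radius,
                 r0, tolerance = 1e-6)
    bp <- basepair_metrics(m2)
    expect_equal(bp$D1, bp0$D1, tolerance = 1e-6)
    expect_equal(bp$theta1, bp0$theta1, tolerance = 1e-6)
    expect_equal(junction_angle(m2, 1), j0, tolerance = 1e-6)
    reg <- registration_check(m2)
    expect_equal(reg$pass, reg0$pass)
    expect_equal(reg$max_dz, reg0$max_dz, tolerance = 1e-6)
  }
})

test_that("extension factor distinguishes B-form from filament DNA", {
  expect_equal(extension_factor(build_bdna("ACGTACGTA"), chain = "A"), 1,
               tolerance = 1e-9)
  ef <- extension_factor(build_filament_strand(strrep("T", 18)))
  expect_equal(ef, 5.1 / 3.38, tolerance = 1e-9)
})

test_that("registration holds for the default model and flags the decoy", {
  m <- default_model()
  reg <- registration_check(m)
  expect_true(all(reg$pass))
  expect_true(attr(reg, "all_pass"))
  dec <- make_scenario(scenario_spec(decoy_mode = "misregistered"))
  reg_d <- registration_check(dec)
  expect_false(attr(reg_d, "all_pass"))
})

test_that("decoys violate exactly their targeted expectation", {
  sII <- fil_meta(default_model())$site_II
  check <- function(model) {
    sm <- step_summary(step_parameters(model, "I", residues = sII$init_res))
    list(
      twist_ok = abs(sm$mean_twist - 20) < 0.5,
      rise_ok = abs(sm$mean_rise - 5.1) < 0.1,
      radius_ok = abs(mean(strand_radius(model, "O",
        residues = sort(sII$outgoing_res))$radius) - 15) < 0.3,
      reg_ok = attr(registration_check(model), "all_pass"),
      junction_ok = abs(junction_angle(model, 1) - 90) < 5)
  }
  base <- check(make_scenario(scenario_spec()))
  expect_true(all(unlist(base)))
  wt <- check(make_scenario(scenario_spec(decoy_mode = "wrong_twist")))
  expect_false(wt$twist_ok)
  expect_true(wt$rise_ok && wt$radius_ok && wt$reg_ok && wt$junction_ok)
  mr <- check(make_scenario(scenario_spec(decoy_mode = "misregistered")))
  expect_false(mr$reg_ok)
  expect_true(mr$twist_ok && mr$rise_ok && mr$radius_ok && mr$junction_ok)
  uk <- check(make_scenario(scenario_spec(decoy_mode = "unkinked")))
  expect_false(uk$junction_ok)
  expect_true(uk$twist_ok && uk$rise_ok && uk$radius_ok && uk$reg_ok)
})

test_that("pairing metrics require the needed annotations", {
  s <- build_filament_strand("TTTTTT")
  expect_error(basepair_metrics(s), "roles")
  d <- annotate_roles(build_bdna("ACGTAC"),
                      c(A = "initiating", B = "complementary"))
  expect_error(basepair_metrics(d), "bookkeeping")
  expect_error(junction_angle(s), "junction")
  expect_error(registration_check(default_model()[1:40, ]), "roles|annotated")
})

test_that("classify_flip applies calibrated thresholds", {
  cfg <- fil_defaults()
  th <- filamentforge:::flip_thresholds(cfg)
  expect_equal(classify_flip(th$d1_paired, th$theta1_paired), "paired")
  expect_equal(classify_flip(th$d1_unflipped, 90), "unflipped")
  mid <- th$d1_paired + 0.4 * (th$d1_unflipped - th$d1_paired)
  expect_equal(classify_flip(mid, 60), "flipping")
})
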