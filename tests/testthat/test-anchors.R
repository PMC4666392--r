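test_that("anchor sets replicate templates along the screw", {
  a <- generate_siteII_anchors(n_monomers = 6)
  expect_s3_class(a, "anchor_set")
  expect_equal(nrow(a), 24)   # 4 labels x 6 monomers
  expect_setequal(unique(a$label), c("R226", "R227", "R243", "K245"))
  # consecutive monomer copies are related by exactly one screw step
  sc <- filament_screw()
  for (lb in unique(a$label)) {
    p1 <- as.numeric(a[a$label == lb & a$monomer == 2, c("x", "y", "z")])
    p0 <- as.numeric(a[a$label == lb & a$monomer == 1, c("x", "y", "z")])
    expect_equal(p1, as.numeric(apply_screw(sc, matrix(p0, 1, 3), 1)),
                 tolerance = 1e-9)
  }
})

test_that("anchor generators validate templates and sizes", {
  expect_error(generate_siteII_anchors(n_monomers = 0), ">= 1")
  expect_error(generate_siteII_anchors(
    template_positions = list(R226 = c(0, 0, 0))), "missing label")
  expect_error(generate_ctd_anchors(
    template_positions = list(K280 = c(0, 0, 0))), "missing label")
  l2 <- generate_l2_anchors(n_monomers = 2)
  expect_equal(nrow(l2), 6)
  both <- bind_anchor_sets(generate_siteII_anchors(n_monomers = 1),
                           generate_ctd_anchors(n_monomers = 1))
  expect_equal(nrow(both), 8)
  expect_error(bind_anchor_sets(), "no anchor sets")
})

test_that("each bound triplet contributes its outgoing duplet phosphates to site II", {
  m <- default_model()
  a <- generate_siteII_anchors(n_monomers = 2)
  sb <- salt_bridge_map(m, a)
  sII <- fil_meta(m)$site_II
  arg <- sb[sb$label %in% c("R226", "R227", "R243"), ]
  for (tr in 1:2) {
    duplet <- sort(sII$outgoing_res[c(3 * tr - 1, 3 * tr)])
    got <- sort(unique(arg$residue_index[arg$monomer == tr & arg$chain == "O"]))
    expect_equal(got, duplet)
    expect_equal(diff(duplet), 1L)   # consecutive phosphates
  }
})

test_that("CTD lysine patch tethers both tail strands over two monomers", {
  m <- default_model()
  a <- generate_ctd_anchors(n_monomers = 2)
  sb <- salt_bridge_map(m, a)
  expect_gte(nrow(dplyr::distinct(sb[, c("chain", "residue_index")])), 4)
  expect_setequal(unique(sb$chain), c("C", "O"))
  expect_setequal(unique(sb$monomer), c(1L, 2L))
})

test_that("flipping the duplet breaks its 5' phosphate salt bridge", {
  m <- default_model()
  a <- generate_siteII_anchors(n_monomers = 2)
  sII <- fil_meta(m)$site_II
  rc <- sII$comp_res[6]   # complementary 5' phosphate of triplet 2's duplet
  before <- salt_bridge_map(m, a)
  expect_true(any(before$label == "K245" & before$chain == "C" &
                    before$residue_index == rc))
  after <- salt_bridge_map(flip_duplet(m, 2), a)
  expect_false(any(after$label == "K245" & after$chain == "C" &
                     after$residue_index == rc))
})

test_that("salt_bridge_map is deterministic and validates inputs", {
  m <- default_model()
  a <- generate_siteII_anchors(n_monomers = 2)
  sb1 <- salt_bridge_map(m, a)
  sb2 <- salt_bridge_map(m, a)
  expect_identical(sb1, sb2)
  expect_true(all(diff(sb1$distance) >= 0))
  expect_true(all(sb1$distance <= fil_defaults()$salt_bridge_cutoff))
  expect_error(salt_bridge_map(m, a[0, ]), "empty anchor")
  expect_error(salt_bridge_map(m, a, cutoff = 0), "> 0")
})
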