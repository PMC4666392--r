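test_that("fil_structure enforces its schema", {
  atoms <- tibble::tibble(chain = "A", residue_index = 1L, residue_name = "DA",
                          atom = "P", element = "P", x = 0, y = 0, z = 0)
  s <- fil_structure(atoms)
  expect_s3_class(s, "fil_structure")
  expect_equal(unname(roles(s)), "scaffold")

  expect_error(fil_structure(atoms[, -1]), "missing column")
  bad <- atoms; bad$x <- NA_real_
  expect_error(fil_structure(bad), "non-finite")
  bad <- atoms; bad$residue_index <- 0L
  expect_error(fil_structure(bad), ">= 1")
  dup <- dplyr::bind_rows(atoms, atoms)
  expect_error(fil_structure(dup), "duplicate atom")
  bad <- atoms; bad$role <- "nonsense"
  expect_error(fil_structure(bad), "invalid role")
})

test_that("annotate_roles assigns and validates roles", {
  d <- build_bdna("ACGTAC")
  d <- annotate_roles(d, c(A = "complementary", B = "outgoing"))
  expect_equal(roles(d)[["A"]], "complementary")
  expect_equal(chain_for_role(d, "outgoing"), "B")
  expect_error(annotate_roles(d, c(Z = "outgoing")), "unknown chain")
  expect_error(annotate_roles(d, c(A = "boss")), "invalid role")
  expect_error(
    annotate_roles(d, c(A = "outgoing", B = "outgoing"), strict = TRUE),
    "duplicate nucleic role")
  # coordinates unchanged by annotation
  expect_equal(coords_of(d), coords_of(annotate_roles(d, c(A = "scaffold"))))
})

test_that("PDB round trip preserves coordinates, chains and residues", {
  m <- default_model()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, path)
  back <- read_pdb(path)
  expect_equal(nrow(back), nrow(m))
  expect_equal(back$chain, m$chain)
  expect_equal(back$residue_index, m$residue_index)
  expect_equal(back$atom, m$atom)
  expect_equal(coords_of(back), coords_of(m), tolerance = 1e-3)
})

test_that("PDB writer emits one TER per chain and an END record", {
  m <- default_model()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "TER")), length(unique(m$chain)))
  expect_equal(sum(startsWith(lines, "END")), 1L)
})

test_that("PDB I/O rejects bad inputs", {
  expect_error(read_pdb(file.path(tempdir(), "no-such-file.pdb")), "not found|exist")
  empty <- fil_structure(tibble::tibble(
    chain = character(), residue_index = integer(), residue_name = character(),
    atom = character(), element = character(),
    x = numeric(), y = numeric(), z = numeric()))
  expect_error(write_pdb(empty, withr::local_tempfile(fileext = ".pdb")),
               "empty|no atoms")
})

test_that("config files parse and reject unknown keys", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "", "bend_angle = 45", "r_outgoing = 14.5"), path)
  cfg <- read_fil_config(path)
  expect_equal(cfg$bend_angle, 45)
  expect_equal(cfg$r_outgoing, 14.5)
  expect_equal(cfg$intra_rise, fil_defaults()$intra_rise)

  writeLines("no_such_key = 1", path)
  expect_error(read_fil_config(path), "unknown default")
  writeLines("just some words", path)
  expect_error(read_fil_config(path), "malformed")
  expect_error(read_fil_config(file.path(tempdir(), "nope.cfg")), "not found")
})

test_that("rigid motions transform coordinates and stored axis together", {
  s <- build_filament_strand("TTTTTT")
  set.seed(11)
  mo <- random_motion()
  s2 <- transform_structure(s, mo$R, mo$t)
  expect_equal(coords_of(s2),
               sweep(coords_of(s) %*% t(mo$R), 2, -mo$t),
               ignore_attr = TRUE)
  ax <- fil_meta(s2)$axis
  expect_equal(ax$direction, as.vector(mo$R %*% c(0, 0, 1)), tolerance = 1e-12)
})
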