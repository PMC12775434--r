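# Molecule, score-table, structure and shortlist I/O.

test_that("SMILES lists round-trip with identical ids and canonical structures", {
  f <- withr::local_tempfile(fileext = ".smi")
  smi <- c("c1ccccc1CCO", "CC(=O)NC", "C1CCNCC1")
  writeLines(paste(smi, c("a", "b", "c"), sep = "\t"), f)
  lib <- read_molecules(f)
  expect_equal(length(lib), 3)
  expect_equal(lib$molecules$id, c("a", "b", "c"))
  expect_equal(nrow(attr(lib, "rejections")), 0)

  # write back out and re-read: canonical structures identical
  f2 <- withr::local_tempfile(fileext = ".smi")
  writeLines(paste(lib$molecules$cansmi, lib$molecules$id, sep = "\t"), f2)
  lib2 <- read_molecules(f2)
  expect_equal(lib2$molecules$id, lib$molecules$id)
  expect_equal(lib2$molecules$cansmi, lib$molecules$cansmi)
})

test_that("empty input gives an empty library and zero rejections", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(character(0), f)
  expect_warning(lib <- read_molecules(f), "empty")
  expect_equal(length(lib), 0)
})

test_that("one malformed record among valid ones is counted, not fatal", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO\tok1", "C1CC\tbad", "CCN\tok2", "c1ccccc1\tok3",
               "CC(C)O\tok4"), f)
  expect_message(lib <- read_molecules(f), "1 record")
  expect_equal(length(lib), 4)
  rej <- attr(lib, "rejections")
  expect_equal(nrow(rej), 1)
  expect_equal(rej$id, "bad")
})

test_that("SDF and mol2 inputs are accepted", {
  smi <- setNames(c("c1ccccc1CCO", "CC(=O)NC"), c("m1", "m2"))
  sdf <- ChemmineR::smiles2sdf(smi)
  f <- withr::local_tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(sdf, f)
  lib <- read_molecules(f)
  expect_equal(length(lib), 2)
  expect_equal(canonical_smiles(smi), lib$molecules$cansmi,
               ignore_attr = TRUE)

  f2 <- withr::local_tempfile(fileext = ".mol2")
  writeLines(ChemmineOB::convertFormat("SMI", "MOL2", "c1ccccc1CCO\tm1\n"),
             f2)
  lib2 <- read_molecules(f2)
  expect_equal(length(lib2), 1)
  expect_equal(lib2$molecules$cansmi, canonical_smiles("c1ccccc1CCO"))
})

test_that("score tables attach and validate against the library", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(molecule_id = c("a", "b"),
                       score_total = c(-42.1, -38.5),
                       electrostatic = c(-20, -15)), f, row.names = FALSE)
  sc <- read_scores(f)
  expect_named(sc, c("molecule_id", "score_total", "electrostatic"))
  lib <- screen_library(c("a", "b"), c("CCO", "CCN"))
  lib <- attach_scores(lib, sc)
  expect_equal(nrow(lib$records), 2)
  expect_error(attach_scores(screen_library("x", "CCO"), sc), "unknown")
})

test_that("shortlists round-trip in rank order; empty needs the flag", {
  sl <- build_shortlist(
    data.frame(representative_id = c("b", "a", "c"),
               representative_score = c(-35, -40, -30),
               size = c(2L, 5L, 1L)),
    n = 2,
    molecules = data.frame(id = c("a", "b", "c"),
                           smiles = c("CCO", "CCN", "CCC"),
                           max_tc_to_known = c(0.2, 0.3, 0.1)))
  expect_equal(sl$id, c("a", "b"))   # -40 then -35
  f <- withr::local_tempfile(fileext = ".csv")
  write_shortlist(sl, f)
  back <- read_shortlist(f)
  expect_equal(back$id, sl$id)
  expect_equal(back$score_total, sl$score_total)

  empty <- sl[0, ]
  expect_error(write_shortlist(empty, f), "allow_empty")
  write_shortlist(empty, f, allow_empty = TRUE)
  expect_equal(nrow(read_shortlist(f)), 0)
})

test_that("structures round-trip through PDB within 1e-3 A", {
  tc <- make_toy_complex(n_pocket_atoms = 12, planted_contacts = 4,
                         seed = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(tc$reference, f)
  back <- read_structure(f, ligand = "LIG")
  expect_equal(sum(back$atoms$ligand), sum(tc$reference$atoms$ligand))
  expect_lt(max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                      as.matrix(tc$reference$atoms[, c("x", "y", "z")]))),
            1e-3)
})

test_that("minimal PDB reads; named ligand must exist; numbering resolves", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A 108      11.000  12.000  13.000  1.00  0.00           C",
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 1)
  expect_equal(sum(m$atoms$ligand), 0)
  expect_error(read_structure(f, ligand = "LIG"), "ligand not found")

  m2 <- read_structure(f, numbering = c("3x32" = 108))
  expect_equal(resolve_label(m2, "3x32"), 108)
  expect_error(resolve_label(m2, "6x51"), "not present")
})
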