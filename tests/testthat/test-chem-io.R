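test_that("empty SDF gives an empty table and empty rejects", {
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(character(0), f)
  mols <- read_molecules(f)
  expect_equal(nrow(mols), 0)
  expect_equal(nrow(mol_rejects(mols)), 0)
})

test_that("a single benzene conformer reads as one record with 6 heavy atoms", {
  f <- withr::local_tempfile(fileext = ".sdf")
  write_molecules(mols_from_smiles("c1ccccc1", "benzene"), f)
  mols <- read_molecules(f)
  expect_equal(nrow(mols), 1)
  expect_equal(hittriage:::heavy_atom_count(mols$mol[[1]]), 6)
})

test_that("corrupt connection tables are rejected, not dropped silently", {
  f <- withr::local_tempfile(fileext = ".sdf")
  sdf_with_corrupt_entry(f)
  mols <- read_molecules(f)
  expect_equal(nrow(mols), 2)
  rej <- mol_rejects(mols)
  expect_equal(nrow(rej), 1)
  expect_equal(rej$reason, "parse")
  expect_equal(rej$index, 2L)
})

test_that("missing input file is fatal", {
  expect_error(read_molecules(file.path(tempdir(), "nope_does_not_exist.sdf")),
               "does not exist")
})

test_that("declared tags round-trip byte-equivalently through write/read", {
  mols <- mols_from_smiles(
    c("CCO", "c1ccccc1", "CC(=O)NC", "CCCCC", "c1ccncc1",
      "CC(C)O", "CCOC", "CCS", "CCN", "Clc1ccccc1"))
  mols$pf_pass <- rep(c(TRUE, FALSE), 5)
  mols$sascore <- round(runif(10, 1, 10), 4)
  mols$delta_g <- round(rnorm(10, -6), 4)
  mols$cluster_id <- sprintf("C%03d", rep(1:2, each = 5))
  f <- withr::local_tempfile(fileext = ".sdf")
  write_molecules(mols, f)
  txt <- readLines(f)
  expect_true(any(txt == ">  <PF_PASS>"))
  expect_true(any(txt == ">  <SAS>"))
  expect_true(any(txt == ">  <GBVI_WSA_dG>"))
  expect_true(any(txt == ">  <CLUSTER_ID>"))
  back <- read_molecules(f)
  expect_equal(back$record_id, mols$record_id)
  expect_equal(back$smiles, mols$smiles)
  expect_equal(back$pf_pass, mols$pf_pass)
  expect_equal(back$sascore, mols$sascore)
  expect_equal(back$delta_g, mols$delta_g)
  expect_equal(back$cluster_id, mols$cluster_id)
})

test_that("records without structures are laid out from SMILES on write", {
  mols <- as_mol_tbl(tibble::tibble(record_id = c("x", "y"),
                                    smiles = c("CCO", "c1ccccc1")))
  f <- withr::local_tempfile(fileext = ".sdf")
  write_molecules(mols, f)
  back <- read_molecules(f)
  expect_equal(nrow(back), 2)
  expect_equal(back$smiles, mols$smiles)
})

test_that("an empty record list writes a valid empty file", {
  mols <- as_mol_tbl(tibble::tibble(record_id = character(0),
                                    smiles = character(0)))
  f <- withr::local_tempfile(fileext = ".sdf")
  write_molecules(mols, f)
  expect_true(file.exists(f))
  expect_equal(nrow(read_molecules(f)), 0)
})

test_that("SMILES files read in order with per-line ids", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1 benzene", "not_a_smiles_$$ bad", "CCO ethanol"), f)
  mols <- read_molecules(f)
  expect_equal(mols$record_id, c("benzene", "ethanol"))
  expect_equal(nrow(mol_rejects(mols)), 1)
})

test_that("validation is total and flags the documented failure classes", {
  good <- mols_from_smiles(c("c1ccccc1", "CCO"))
  rep_good <- validate_molecules(good)
  expect_true(all(rep_good$is_valid))
  expect_true(all(lengths(rep_good$failures) == 0))

  bad <- mol_tbl(c("penta", "weird", "ghost"),
                 c("C", "C", "C"),
                 list(pentavalent_carbon_sdf(), unknown_element_sdf(), NULL))
  rep_bad <- validate_molecules(bad)
  expect_false(any(rep_bad$is_valid))
  expect_true("valence" %in% rep_bad$failures[[1]])
  expect_true("atom_type" %in% rep_bad$failures[[2]])
  expect_true("parse" %in% rep_bad$failures[[3]])
  # is_valid <=> empty failure list
  expect_equal(rep_bad$is_valid, lengths(rep_bad$failures) == 0)
})

test_that("round trip preserves count, canonical SMILES and formal charges", {
  smis <- c("C(=O)([O-])Cc1ccccc1C[NH3+]", "CC(=O)Oc1ccccc1C(=O)O", "O")
  mols <- mols_from_smiles(smis)
  f <- withr::local_tempfile(fileext = ".sdf")
  write_molecules(mols, f)
  back <- read_molecules(f)
  expect_equal(nrow(back), 3)
  expect_equal(back$smiles, mols$smiles)
  g <- hittriage:::mol_graph(back$mol[[1]])
  expect_equal(sum(g$charge == 1), 1)
  expect_equal(sum(g$charge == -1), 1)
})
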