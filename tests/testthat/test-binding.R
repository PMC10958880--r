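toy_setup <- function(smiles = "CC(C)CCO") {
  rec <- generate_toy_receptor(pocket_radius = 6, n_shell = 50, charge = -2)
  sdf <- translate_conformer(hittriage:::conformer_from_smiles(smiles),
                             center = c(0, 0, 0))
  list(rec = rec, mols = mol_tbl("lig", smiles, list(sdf)), sdf = sdf)
}

test_that("the stored terms satisfy the score identity", {
  s <- toy_setup()
  p <- binding_params()
  out <- score_binding(s$mols, s$rec, p)
  rhs <- p$c + p$alpha * ((2 / 3) * (out$e_coul + out$e_sol) + out$e_vdw +
                            p$beta * out$sa_weighted)
  expect_equal(out$delta_g, rhs, tolerance = 1e-9)
})

test_that("a ligand 50 A from the pocket scores approximately c", {
  s <- toy_setup()
  far <- mol_tbl("far", "CC(C)CCO",
                 list(translate_conformer(s$sdf, offset = c(50, 0, 0))))
  out <- score_binding(far, s$rec, binding_params(c = 1.5))
  expect_lt(abs(out$e_coul), 0.2)
  expect_lt(abs(out$e_vdw), 0.05)
  expect_lt(abs(out$sa_weighted), 1e-6)
  expect_equal(out$delta_g, 1.5, tolerance = 0.2)
})

test_that("the bound pose scores no worse than the displaced pose", {
  s <- toy_setup()
  bound <- score_binding(s$mols, s$rec)
  far <- score_binding(
    mol_tbl("far", "CC(C)CCO",
            list(translate_conformer(s$sdf, offset = c(50, 0, 0)))),
    s$rec)
  expect_lte(bound$delta_g, far$delta_g)
})

test_that("alpha = 0 collapses the score to c for any pose", {
  s <- toy_setup()
  p <- binding_params(c = -2.25, alpha = 0)
  out <- score_binding(s$mols, s$rec, p)
  expect_equal(out$delta_g, -2.25)
})

test_that("an externally supplied score wins over the surrogate", {
  s <- toy_setup()
  s$mols$delta_g <- -9.25
  out <- score_binding(s$mols, s$rec)
  expect_equal(out$delta_g, -9.25)
})

test_that("clashing poses are flagged but still scored", {
  rec <- generate_toy_receptor(pocket_radius = 2, n_shell = 30)
  sdf <- translate_conformer(hittriage:::conformer_from_smiles("CCCCCC"),
                             center = c(0, 0, 0))
  out <- score_binding(mol_tbl("big", "CCCCCC", list(sdf)), rec)
  expect_true(out$clash)
  expect_true(is.finite(out$delta_g))
})

test_that("a ligand centred in the pocket has attractive vdW contact", {
  rec <- generate_toy_receptor(pocket_radius = 5, n_shell = 60)
  sdf <- translate_conformer(hittriage:::conformer_from_smiles("C1CCCCC1"),
                             center = c(0, 0, 0))
  out <- score_binding(mol_tbl("chx", "C1CCCCC1", list(sdf)), rec)
  expect_lt(out$e_vdw, 0)
})

test_that("toy receptors are deterministic and PDB round-trips", {
  r1 <- generate_toy_receptor(pocket_radius = 5, n_shell = 40)
  r2 <- generate_toy_receptor(pocket_radius = 5, n_shell = 40)
  expect_identical(r1, r2)
  f <- withr::local_tempfile(fileext = ".pdb")
  cs <- withr::local_tempfile(fileext = ".csv")
  write_receptor_pdb(r1, f, cs)
  r3 <- read_receptor(f, cs)
  expect_equal(nrow(r3), nrow(r1))
  expect_equal(r3$x, r1$x, tolerance = 1e-3)
  expect_equal(r3$charge, r1$charge)
  # minimal shell is still a valid PDB
  rmin <- generate_toy_receptor(n_shell = 4)
  expect_gte(nrow(rmin), 4)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_receptor_pdb(rmin, f2)
  expect_gte(nrow(read_receptor(f2)), 4)
})
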