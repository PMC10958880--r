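test_that("QED equals 1 when every desirability is 1", {
  expect_equal(qed_from_desirabilities(rep(1, 8)), 1)
  expect_equal(qed_from_desirabilities(rep(1, 8), qed_weights("unit")), 1)
})

test_that("equal weights reduce QED to the plain geometric mean", {
  set.seed(1)
  for (k in 1:5) {
    d <- runif(8, 0.05, 1)
    expect_equal(qed_from_desirabilities(d, qed_weights("unit")),
                 prod(d)^(1 / 8), tolerance = 1e-12)
  }
})

test_that("degenerate weighting returns the single desirability", {
  w <- setNames(c(1, rep(0, 7)), names(qed_weights("unit")))
  expect_equal(qed_from_desirabilities(c(0.25, rep(0.9, 7)), w), 0.25)
})

test_that("QED is invariant under proportional weight rescaling", {
  set.seed(7)
  d <- runif(8, 0.1, 1)
  w <- qed_weights("mean")
  expect_equal(qed_from_desirabilities(d, w),
               qed_from_desirabilities(d, qed_weights(as.numeric(w * 3.7))),
               tolerance = 1e-12)
})

test_that("a zero desirability yields QED 0 with a warning", {
  expect_warning(q <- qed_from_desirabilities(c(0, rep(1, 7))), "zero")
  expect_equal(q, 0)
})

test_that("computed QED lies in [0, 1] across diverse molecules", {
  mols <- mols_from_smiles(c(
    "CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O",
    "CCN(CC)CC(=O)Nc1c(C)cccc1C", "O", "C",
    "c1ccc2c(c1)cccc2", "[O-]C(=O)c1ccccc1"))
  q <- compute_qed(mols)
  expect_true(all(q$qed >= 0 & q$qed <= 1))
})

test_that("SAscore is deterministic and ranks simple molecules as easy", {
  mols <- mols_from_smiles(c("CCO", "CCO", "CC(C)CO"),
                           c("a", "b", "c"))
  s <- compute_sascore(mols)
  expect_identical(s$sascore[1], s$sascore[2])
  expect_lte(s$sascore[1], 3)
  expect_true(all(s$sascore >= 1 & s$sascore <= 10))
})

test_that("stereo-rich fused polycyclics score harder than flat analogues", {
  # fused polycyclic with four marked stereocentres vs the flattened
  # aromatic analogue of the same ring count
  hard <- "C1C[C@H]2[C@@H]3CC[C@H]4CC[C@@H](C1)C2C34"
  flat <- "c1ccc2c(c1)ccc1ccccc21"
  s <- compute_sascore(mols_from_smiles(c(hard, flat), c("hard", "flat")))
  expect_gt(s$sascore[s$record_id == "hard"],
            s$sascore[s$record_id == "flat"])
})

test_that("empty molecules cannot be scored", {
  expect_error(hittriage:::sascore_one(
    methods::new("SDF"), "", default_fragment_table()))
})

test_that("hit calling applies the published inclusive boundaries", {
  tbl <- as_mol_tbl(tibble::tibble(
    record_id = c("edge", "sas_fail", "qed_fail"),
    smiles = NA_character_,
    sascore = c(4.0, 4.01, 2),
    qed = c(0.5, 0.9, 0.49),
    delta_g = c(-6.0, -8, -8)))
  out <- apply_hit_filters(tbl)
  expect_equal(out$is_virtual_hit, c(TRUE, FALSE, FALSE))
  expect_equal(out$sas_pass, c(TRUE, FALSE, TRUE))
  expect_equal(out$qed_pass, c(TRUE, TRUE, FALSE))
  expect_true(all(out$is_virtual_hit ==
                    (out$sas_pass & out$qed_pass & out$dg_pass)))
})

test_that("hit calling is monotone in each cutoff", {
  set.seed(11)
  tbl <- as_mol_tbl(tibble::tibble(
    record_id = sprintf("r%02d", 1:40), smiles = NA_character_,
    sascore = runif(40, 1, 8), qed = runif(40),
    delta_g = runif(40, -10, 0)))
  base <- apply_hit_filters(tbl)$is_virtual_hit
  looser <- apply_hit_filters(tbl, hit_cutoffs(sas_max = 5, qed_min = 0.4,
                                               dg_max = -5))$is_virtual_hit
  expect_true(all(looser | !base))
})
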