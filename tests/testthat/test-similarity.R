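conf3d <- function(smiles) {
  translate_conformer(hittriage:::conformer_from_smiles(smiles),
                      center = c(0, 0, 0))
}

rigid_transform <- function(sdf, angles = c(0.3, 1.1, -0.7),
                            shift = c(4, -2, 9)) {
  Rx <- matrix(c(1, 0, 0, 0, cos(angles[1]), -sin(angles[1]),
                 0, sin(angles[1]), cos(angles[1])), 3, byrow = TRUE)
  Ry <- matrix(c(cos(angles[2]), 0, sin(angles[2]), 0, 1, 0,
                 -sin(angles[2]), 0, cos(angles[2])), 3, byrow = TRUE)
  Rz <- matrix(c(cos(angles[3]), -sin(angles[3]), 0,
                 sin(angles[3]), cos(angles[3]), 0, 0, 0, 1), 3, byrow = TRUE)
  ab <- ChemmineR::atomblock(sdf)
  ab[, 1:3] <- ab[, 1:3] %*% (Rx %*% Ry %*% Rz)
  methods::slot(sdf, "atomblock") <- ab
  translate_conformer(sdf, offset = shift)
}

test_that("self-similarity is a perfect combo of 2", {
  m <- mol_tbl("q", "CC(C)c1ccc(O)cc1", list(conf3d("CC(C)c1ccc(O)cc1")))
  sim <- shape_feature_similarity(m, m)
  expect_equal(sim$shape_tanimoto, 1, tolerance = 1e-6)
  expect_equal(sim$feature_tanimoto, 1, tolerance = 1e-6)
  expect_equal(sim$combo, 2, tolerance = 1e-6)
  expect_equal(sim$combo, sim$shape_tanimoto + sim$feature_tanimoto)
})

test_that("combo is invariant to rigid pre-transformation of one copy", {
  base <- conf3d("CCOc1ccccc1CN")
  m1 <- mol_tbl("a", "CCOc1ccccc1CN", list(base))
  m2 <- mol_tbl("b", "CCOc1ccccc1CN", list(rigid_transform(base)))
  sim <- shape_feature_similarity(m1, m2)
  expect_equal(sim$combo, 2, tolerance = 1e-3)
})

test_that("molecules with no common feature types score feature 0", {
  alkane <- mol_tbl("alk", "CCCCCC", list(conf3d("CCCCCC")))   # hydrophobes only
  diol <- mol_tbl("diol", "OCCO", list(conf3d("OCCO")))        # donors/acceptors
  sim <- shape_feature_similarity(alkane, diol)
  expect_equal(sim$feature_tanimoto, 0)
})

test_that("missing conformers raise a user-facing error", {
  flat <- mol_tbl("no3d", "CCO", list(NULL))
  m <- mol_tbl("q", "CCO", list(conf3d("CCO")))
  expect_error(shape_feature_similarity(m, flat), "3-D|conformer|SDF")
})

test_that("library search keeps best matches above the cutoff, ordered", {
  smis <- c("CCc1ccccc1", "CCCc1ccccc1", "OCCN")
  lib <- mol_tbl(paste0("L", 1:3), smis, lapply(smis, conf3d))
  hits <- search_library(lib, lib, combo_cutoff = 1.0)
  # every query matches itself at combo 2
  expect_true(all(paste0("L", 1:3) %in% hits$candidate_id))
  self <- hits[hits$candidate_id == hits$query_id, ]
  expect_true(all(self$combo > 1.99))
  expect_true(!is.unsorted(rev(hits$combo)))
  # an impossible cutoff removes everything
  none <- search_library(lib[1, ], lib[2:3, ], combo_cutoff = 2 + 1e-6)
  expect_equal(nrow(none), 0)
  # raising the cutoff never adds candidates
  lo <- search_library(lib[1, ], lib, combo_cutoff = 0.5)
  hi <- search_library(lib[1, ], lib, combo_cutoff = 1.5)
  expect_true(all(hi$candidate_id %in% lo$candidate_id))
})

test_that("rescoring applies the dG cutoff then predicates in order", {
  cand <- score_table(rep("A", 10), c(rep(-7, 4), rep(-3, 6)))
  cand$quantity_ok <- c(TRUE, TRUE, FALSE, FALSE, rep(TRUE, 6))
  cand$qc_ok <- TRUE
  rep <- rescore_and_filter(cand, dg_cutoff = -6,
                            predicates = list(quantity_ok = "quantity_ok",
                                              qc_ok = "qc_ok"))
  g <- glance(rep)
  expect_equal(g$n_library, 10)
  expect_equal(g$n_past_dg, 4)
  expect_equal(g$n_past_predicates, 2)
  # counts are monotone along the chain
  expect_true(all(diff(c(g$n_library, g$n_past_combo, g$n_past_dg,
                         g$n_past_predicates)) <= 0))
  # empty predicate list keeps the dG survivors
  rep2 <- rescore_and_filter(cand, dg_cutoff = -6)
  expect_equal(rep2$n_past_predicates, 4)
  # an always-false predicate empties the selection, upstream intact
  rep3 <- rescore_and_filter(cand, dg_cutoff = -6,
                             predicates = list(nope = function(x) rep(FALSE, nrow(x))))
  expect_equal(rep3$n_past_predicates, 0)
  expect_equal(unname(rep3$stage_counts["n_past_dg"]), 4)
})
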