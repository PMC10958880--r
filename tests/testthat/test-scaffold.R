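test_that("Murcko assemblies keep rings and linkers, drop side chains", {
  mols <- mols_from_smiles(
    c("c1ccccc1", "Cc1ccccc1", "CCCCCC", "c1ccc(CCc2ccccc2)cc1",
      "CCc1ccc(cc1)C(=O)N1CCOCC1"),
    c("benzene", "toluene", "hexane", "bibenzyl", "decorated"))
  out <- murcko_assembly(mols)
  expect_equal(out$scaffold_smiles[out$record_id == "benzene"], "c1ccccc1")
  expect_equal(out$scaffold_smiles[out$record_id == "toluene"], "c1ccccc1")
  expect_equal(out$scaffold_smiles[out$record_id == "hexane"], "")
  # the two-ring linker is retained
  expect_equal(out$scaffold_smiles[out$record_id == "bibenzyl"],
               canonical_smiles_of("c1ccc(CCc2ccccc2)cc1"))
  # exocyclic carbonyl on the amide linker survives; the ethyl does not
  dec <- out$scaffold_smiles[out$record_id == "decorated"]
  expect_equal(dec, canonical_smiles_of("O=C(c1ccccc1)N1CCOCC1"))
})

test_that("scaffold extraction is idempotent", {
  smis <- c("Cc1ccccc1", "CCc1ccc(cc1)C(=O)N1CCOCC1",
            "c1ccc2[nH]ccc2c1", "CC1CCN(CC1)c1ncccn1")
  first <- murcko_assembly(mols_from_smiles(smis))$scaffold_smiles
  again <- murcko_assembly(mols_from_smiles(first))$scaffold_smiles
  expect_equal(again, first)
})

test_that("fingerprints are deterministic with the documented conventions", {
  fp1 <- scaffold_fingerprint(c("c1ccccc1", "c1ccccc1"))
  expect_identical(fp1[1, ], fp1[2, ])
  expect_equal(tanimoto(fp1[1, ], fp1[2, ]), 1)
  fp2 <- scaffold_fingerprint(c("c1ccccc1", "C1CCCCC1"))
  expect_lt(tanimoto(fp2[1, ], fp2[2, ]), 1)
  # empty scaffold: reserved all-zero vector
  fp3 <- scaffold_fingerprint(c("", "c1ccccc1"))
  expect_equal(sum(fp3[1, ]), 0)
  expect_equal(ncol(fp3), 2048)
})

test_that("identical points collapse to one cluster of size n", {
  mols <- mols_from_smiles(rep("Cc1ccccc1", 6))
  mols <- murcko_assembly(mols)
  cl <- cluster_scaffolds(mols)
  expect_equal(length(cl$centers), 1)
  expect_equal(unname(cl$cluster_sizes["C001"]), 6L)
})

test_that("mutually distant points become singletons", {
  # unrelated ring systems with pairwise scaffold distance > 0.625
  smis <- c("c1ccccc1", "C1CCNCC1", "c1ccc2c(c1)nc(N)s2", "C1CCOC1")
  mols <- murcko_assembly(mols_from_smiles(smis))
  fp <- scaffold_fingerprint(mols$scaffold_smiles)
  d <- hittriage:::tanimoto_distance_matrix(fp)
  stopifnot(all(d[upper.tri(d)] > 0.625))
  cl <- cluster_scaffolds(mols)
  expect_equal(length(cl$centers), 4)
  expect_true(all(cl$cluster_sizes == 1))
})

test_that("clustering matches the naive oracle and its invariants", {
  set.seed(101)
  for (trial in 1:25) {
    fp <- random_fp_matrix(20, 64)
    ids <- sprintf("id%02d", 1:20)
    d <- hittriage:::tanimoto_distance_matrix(fp)
    g <- hittriage:::greedy_maxdis(d, ids, max_distance = 0.625)
    o <- maxdis_oracle(d, ids, max_distance = 0.625)
    expect_equal(g$center_u, o$centers)
    expect_equal(g$assign_u, o$assign)
    # coverage: every member within the cap of its own center
    own <- d[cbind(seq_len(20), g$center_u[g$assign_u])]
    expect_true(all(own <= 0.625 + 1e-12))
    # separation: centers pairwise beyond the cap
    if (length(g$center_u) > 1) {
      dc <- d[g$center_u, g$center_u]
      expect_true(all(dc[upper.tri(dc)] > 0.625))
    }
  }
})

test_that("clustering is deterministic and label-stable under permutation", {
  set.seed(77)
  fp <- random_fp_matrix(15, 64)
  ids <- sprintf("id%02d", 1:15)
  d <- hittriage:::tanimoto_distance_matrix(fp)
  g1 <- hittriage:::greedy_maxdis(d, ids)
  g2 <- hittriage:::greedy_maxdis(d, ids)
  expect_identical(g1, g2)
  # permute input order: same partition up to relabelling
  perm <- sample(15)
  gp <- hittriage:::greedy_maxdis(d[perm, perm], ids[perm])
  part1 <- split(seq_len(15), g1$assign_u)
  part2 <- split(perm, gp$assign_u)
  norm <- function(p) unname(lapply(p, sort))[order(vapply(lapply(p, sort),
                                                           min, numeric(1)))]
  expect_equal(norm(part1), norm(part2))
})

test_that("annotation conserves sizes and is idempotent", {
  spec <- library_spec(n_molecules = 120, seed = 9)
  recs <- generate_library(spec)$records
  recs <- murcko_assembly(recs)
  cl <- cluster_scaffolds(recs)
  a1 <- annotate_clusters(recs, cl)
  expect_equal(sum(dplyr::distinct(a1, cluster_id, cluster_size)$cluster_size),
               nrow(a1))
  a2 <- annotate_clusters(a1, cl)
  expect_identical(a1, a2)
  singleton <- annotate_clusters(recs[1, ],
                                 cluster_scaffolds(murcko_assembly(recs[1, ])))
  expect_equal(singleton$cluster_size, 1L)
})
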