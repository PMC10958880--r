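# Shared fixtures built in code: tiny molecule tables, hand-written SDF
# blocks (including deliberately broken ones), and an independent
# brute-force Fisher oracle.

mols_from_smiles <- function(smiles, ids = NULL) {
  ids <- ids %||% sprintf("m%03d", seq_along(smiles))
  mol_tbl(ids, smiles, lapply(smiles, smiles_to_sdf_one))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

canonical_smiles_of <- function(s) hittriage:::canonical_smiles(s)

# A valid 3-entry SDF with the middle connection table corrupted.
sdf_with_corrupt_entry <- function(path) {
  good1 <- hittriage:::sdf_block_lines(smiles_to_sdf_one("CCO"), "ok_1")
  good2 <- hittriage:::sdf_block_lines(smiles_to_sdf_one("c1ccccc1"), "ok_2")
  bad <- c("broken", "  hittriage", "",
           "  3  2  0  0  0  0  0  0  0  0999 V2000",
           "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    2.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
           "  1  9  1  0  0  0  0",   # bond to a non-existent atom
           "  2  3  1  0  0  0  0",
           "M  END")
  writeLines(c(good1, "$$$$", bad, "$$$$", good2, "$$$$"), path)
  path
}

# Hand-built molblock with a pentavalent carbon (5 single bonds).
pentavalent_carbon_sdf <- function() {
  lines <- c("pentaC", "  hittriage", "",
             "  6  5  0  0  0  0  0  0  0  0999 V2000",
             "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
             "    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
             "   -1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
             "    0.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
             "    0.0000   -1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
             "    0.0000    0.0000    1.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
             "  1  2  1  0  0  0  0",
             "  1  3  1  0  0  0  0",
             "  1  4  1  0  0  0  0",
             "  1  5  1  0  0  0  0",
             "  1  6  1  0  0  0  0",
             "M  END")
  hittriage:::parse_molblock(lines)
}

# Hand-built molblock with an unknown element symbol.
unknown_element_sdf <- function() {
  lines <- c("weird", "  hittriage", "",
             "  2  1  0  0  0  0  0  0  0  0999 V2000",
             "    0.0000    0.0000    0.0000 Xx  0  0  0  0  0  0  0  0  0  0  0  0",
             "    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
             "  1  2  1  0  0  0  0",
             "M  END")
  hittriage:::parse_molblock(lines)
}

# Independent brute-force Fisher oracle: enumerate every table with the
# observed margins, point probabilities from plain factorial products.
fisher_oracle <- function(a, b, c, d, alternative = "greater") {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  point <- vapply(xs, function(x) {
    (factorial(r1) * factorial(n - r1) * factorial(c1) * factorial(n - c1)) /
      (factorial(x) * factorial(r1 - x) * factorial(c1 - x) *
         factorial(n - r1 - c1 + x) * factorial(n))
  }, numeric(1))
  obs <- point[xs == a]
  if (alternative == "greater") {
    sum(point[xs >= a])
  } else {
    sum(point[point <= obs * (1 + 1e-7)])
  }
}

# Independent molecule-level greedy max-dissimilarity oracle (naive O(n^2)
# loops, no unique-point optimisation), following the documented rules.
maxdis_oracle <- function(dmat, ids, max_distance) {
  n <- nrow(dmat)
  sums <- rowSums(dmat)
  cand <- which(sums == max(sums))
  first <- cand[order(ids[cand])][1]
  centers <- first
  repeat {
    nearest <- apply(dmat[, centers, drop = FALSE], 1, min)
    far <- max(nearest)
    if (far <= max_distance) break
    cand <- which(nearest == far)
    centers <- c(centers, cand[order(ids[cand])][1])
  }
  assign <- apply(dmat[, centers, drop = FALSE], 1, which.min)
  list(centers = centers, assign = assign)
}

# Random 0/1 fingerprint matrix for clustering property tests.
random_fp_matrix <- function(n, bits, density = 0.2) {
  matrix(as.integer(runif(n * bits) < density), nrow = n)
}

# Label-level score table for enrichment tests (no chemistry needed).
score_table <- function(cluster_id, delta_g, sas_pass = TRUE,
                        qed_pass = TRUE) {
  n <- length(cluster_id)
  as_mol_tbl(tibble::tibble(
    record_id = sprintf("r%05d", seq_len(n)),
    smiles = NA_character_,
    cluster_id = cluster_id,
    delta_g = delta_g,
    sas_pass = rep_len(sas_pass, n),
    qed_pass = rep_len(qed_pass, n)
  ))
}
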