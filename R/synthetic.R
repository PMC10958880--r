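# Seed-deterministic synthetic compound libraries with planted structure.
# Molecules are built by decorating scaffold templates (SMILES with `R`
# substitution slots) from a fixed substituent menu, so scaffold identity
# (and hence cluster structure) is controlled exactly; binding scores come
# from a per-cluster Gaussian score model, with optional planted enrichment
# expressed as a hit-odds multiplier at the reference cutoff. One integer
# seed drives all randomness through a single generator stream.

.default_scaffold_pool <- c(
  "c1ccc(R)cc1",                 # benzene
  "c1ccnc(R)c1",                 # pyridine
  "c1ccc2[nH]c(R)cc2c1",         # indole
  "C1CCN(CC1)C(=O)R",            # piperidine amide
  "c1ccc(cc1)c1ccc(R)cc1",       # biphenyl
  "c1cnc2ccc(R)cc2c1",           # quinoline-like
  "C1CCC(CC1)c1ccc(R)cc1",       # cyclohexyl-phenyl
  "c1cc(R)cnc1N",                # aminopyridine
  "c1csc(R)c1",                  # thiophene
  "O=C1NC(=O)c2ccccc12"          # phthalimide (no slot)
)

.default_substituents <- c("C", "CC", "CCC", "CC(C)C", "CCO", "OC", "N",
                           "NC", "Cl", "F", "C(=O)O", "C(=O)NC", "OCC",
                           "CN(C)C", "C#N", "")

#' Specification for a synthetic compound library
#'
#' @param n_molecules Library size.
#' @param scaffold_pool SMILES templates; the token `R` marks substitution
#'   slots (an empty substituent removes the slot).
#' @param cluster_proportions Sampling proportions per scaffold (sum 1);
#'   default uniform.
#' @param substituents Decoration menu.
#' @param dg_mean,dg_sd Baseline binding-score distribution (kcal/mol).
#' @param dg_cluster_shift Per-scaffold additive shift (recycled).
#' @param planted_enriched Integer indices into `scaffold_pool` whose hit
#'   odds are multiplied.
#' @param hit_odds_multiplier Odds multiplier for planted scaffolds at the
#'   reference cutoff.
#' @param dg_ref Reference cutoff defining a "hit" for planting (default -6).
#' @param seed Integer seed; all generation randomness derives from it.
#' @return A `library_spec` list.
#' @export
library_spec <- function(n_molecules = 1000,
                         scaffold_pool = .default_scaffold_pool,
                         cluster_proportions = NULL,
                         substituents = .default_substituents,
                         dg_mean = -4.5, dg_sd = 1.2,
                         dg_cluster_shift = 0,
                         planted_enriched = integer(0),
                         hit_odds_multiplier = 20,
                         dg_ref = -6,
                         seed = 1) {
  k <- length(scaffold_pool)
  if (is.null(cluster_proportions)) cluster_proportions <- rep(1 / k, k)
  stopifnot(length(cluster_proportions) == k,
            abs(sum(cluster_proportions) - 1) < 1e-8,
            all(planted_enriched %in% seq_len(k)))
  structure(list(
    n_molecules = n_molecules, scaffold_pool = scaffold_pool,
    cluster_proportions = cluster_proportions, substituents = substituents,
    dg_mean = dg_mean, dg_sd = dg_sd,
    dg_cluster_shift = rep_len(dg_cluster_shift, k),
    planted_enriched = as.integer(planted_enriched),
    hit_odds_multiplier = hit_odds_multiplier,
    dg_ref = dg_ref, seed = as.integer(seed)
  ), class = "library_spec")
}

decorate_template <- function(template, substituents, pick) {
  out <- template
  while (grepl("R", out, fixed = TRUE)) {
    s <- substituents[pick()]
    rep_with <- if (nzchar(s)) s else ""
    if (!nzchar(rep_with)) {
      out <- sub("(R)", "", out, fixed = TRUE)
      out <- sub("R", "", out, fixed = TRUE)
    } else {
      out <- sub("R", rep_with, out, fixed = TRUE)
    }
  }
  out
}

#' Generate a synthetic library with planted truth
#'
#' Draws scaffold assignments from the cluster proportions, decorates the
#' scaffold templates, and draws binding scores from the score model. For
#' planted scaffolds the hit probability at `dg_ref` is inflated to the
#' requested odds multiplier and scores are redrawn from the matching
#' truncated normal, so the marginal per-cluster score distribution remains
#' the stated Gaussian family.
#'
#' @param spec A [library_spec()].
#' @param structures Build SMILES and 2-D structures (`TRUE`) or emit a
#'   label-level table only (`FALSE`; much faster, used for large
#'   simulation studies where only cluster/score structure matters).
#' @param conformers Additionally embed deterministic 3-D conformers
#'   (slower; needed only by the shape and binding modules).
#' @return A list: `records` (molecule table with `cluster_id`, `delta_g`,
#'   `sascore`, `qed`, `sas_pass`, `qed_pass` columns) and `truth` (list
#'   with `scaffold_index` per record, `truly_enriched` per scaffold, and
#'   the per-record true score).
#' @export
generate_library <- function(spec, structures = TRUE, conformers = FALSE) {
  stopifnot(inherits(spec, "library_spec"))
  set.seed(spec$seed)
  k <- length(spec$scaffold_pool)
  n <- spec$n_molecules
  scaf_idx <- sample.int(k, n, replace = TRUE, prob = spec$cluster_proportions)
  mu <- spec$dg_mean + spec$dg_cluster_shift[scaf_idx]
  dg <- rnorm(n, mean = mu, sd = spec$dg_sd)

  planted <- scaf_idx %in% spec$planted_enriched
  if (any(planted) && spec$hit_odds_multiplier != 1) {
    p0 <- stats::pnorm(spec$dg_ref, mean = mu[planted], sd = spec$dg_sd)
    odds1 <- spec$hit_odds_multiplier * p0 / (1 - p0)
    p1 <- odds1 / (1 + odds1)
    is_hit <- runif(sum(planted)) < p1
    # truncated-normal redraw consistent with the hit label
    u <- runif(sum(planted))
    q0 <- stats::pnorm(spec$dg_ref, mu[planted], spec$dg_sd)
    dg_new <- ifelse(
      is_hit,
      stats::qnorm(u * q0, mu[planted], spec$dg_sd),
      stats::qnorm(q0 + u * (1 - q0), mu[planted], spec$dg_sd)
    )
    dg[planted] <- dg_new
  }

  ids <- sprintf("syn_%05d", seq_len(n))
  sub_pick_state <- sample.int(length(spec$substituents), n * 4, replace = TRUE)
  pick_ptr <- 0L
  pick <- function() {
    pick_ptr <<- pick_ptr + 1L
    sub_pick_state[pick_ptr]
  }

  if (structures) {
    smiles_raw <- vapply(scaf_idx, function(si) {
      decorate_template(spec$scaffold_pool[si], spec$substituents, pick)
    }, character(1))
    can <- canonical_smiles(smiles_raw)
    mol <- purrr::map(seq_len(n), function(i) {
      if (is.na(can[i])) return(NULL)
      if (conformers) {
        sdf <- conformer_from_smiles(smiles_raw[i])
        if (!is.null(sdf)) return(sdf)
      }
      smiles_to_sdf_one(smiles_raw[i])
    })
    records <- mol_tbl(ids, can, mol, canonicalize = FALSE)
  } else {
    records <- as_mol_tbl(tibble::tibble(record_id = ids,
                                         smiles = NA_character_))
  }
  records$cluster_id <- sprintf("S%02d", scaf_idx)
  records$delta_g <- dg
  # generated chemistry is deliberately easy and drug-like; the secondary
  # scores are drawn near-passing so the hit predicate is score-driven
  records$sascore <- pmin(pmax(rnorm(n, 2.5, 0.5), 1), 10)
  records$qed <- pmin(pmax(rnorm(n, 0.7, 0.08), 0), 1)
  records$sas_pass <- records$sascore <= 4
  records$qed_pass <- records$qed >= 0.5

  truth <- list(
    scaffold_index = setNames(scaf_idx, ids),
    truly_enriched = setNames(seq_len(k) %in% spec$planted_enriched,
                              sprintf("S%02d", seq_len(k))),
    true_delta_g = setNames(dg, ids)
  )
  list(records = records, truth = truth)
}

#' Null library: hit labels independent of cluster
#'
#' Convenience wrapper for type-I-error studies: a [generate_library()] call
#' with no planted scaffolds and no per-cluster shift, so the binding scores
#' (and therefore hit labels at any cutoff) are exchangeable across
#' clusters.
#'
#' @param spec A [library_spec()]; its `planted_enriched` and
#'   `dg_cluster_shift` are ignored.
#' @param structures,conformers See [generate_library()].
#' @return The records table.
#' @export
null_library <- function(spec, structures = FALSE, conformers = FALSE) {
  spec$planted_enriched <- integer(0)
  spec$dg_cluster_shift <- rep(0, length(spec$scaffold_pool))
  generate_library(spec, structures = structures,
                   conformers = conformers)$records
}

# 3-D conformer via OpenBabel coordinate generation; header normalized so
# output is byte-stable.
conformer_from_smiles <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat(
      "SMI", "SDF", source = smiles,
      options = data.frame(names = "gen3d", args = "", stringsAsFactors = FALSE)),
    error = function(e) NA_character_)
  if (is.na(out)) return(NULL)
  parse_molblock(strsplit(out, "\n")[[1]])
}

#' Generate a toy receptor pocket
#'
#' A concave spherical shell of pseudo-atoms with an opening, centred at the
#' origin: a deterministic geometry for exercising the binding scorer's
#' non-interacting limit and bound-versus-displaced ordering. Shell points
#' are placed on a golden spiral (no RNG needed); a fraction carries partial
#' charges.
#'
#' @param pocket_radius Shell radius in Angstrom.
#' @param n_shell Number of shell atoms (minimum 4).
#' @param opening_fraction Fraction of the sphere removed to form the mouth.
#' @param charge Total charge spread over every third shell atom.
#' @return A `receptor` tibble (`serial, element, x, y, z, charge, radius`).
#' @export
generate_toy_receptor <- function(pocket_radius = 5, n_shell = 60,
                                  opening_fraction = 0.25, charge = 0) {
  n_shell <- max(4L, as.integer(n_shell))
  pts <- sphere_points(n_shell) * pocket_radius
  keep <- pts[, 3] < pocket_radius * (1 - 2 * opening_fraction)
  if (sum(keep) < 4) keep[seq_len(4)] <- TRUE
  pts <- pts[keep, , drop = FALSE]
  q <- rep(0, nrow(pts))
  if (charge != 0) {
    slots <- seq(1, nrow(pts), by = 3)
    q[slots] <- charge / length(slots)
  }
  rec <- tibble::tibble(
    serial = seq_len(nrow(pts)), element = "C",
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    charge = q, radius = 1.7
  )
  class(rec) <- c("receptor", class(rec))
  rec
}

#' Write a receptor to PDB (plus optional charge sidecar CSV)
#'
#' @param receptor A `receptor` tibble.
#' @param path Output PDB path.
#' @param charges_path Optional sidecar CSV path
#'   (`atom_serial, charge, radius`).
#' @return Invisibly, `path`.
#' @export
write_receptor_pdb <- function(receptor, path, charges_path = NULL) {
  lines <- vapply(seq_len(nrow(receptor)), function(i) {
    sprintf("HETATM%5d  %-3s PKT A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            receptor$serial[i], receptor$element[i], 1L,
            receptor$x[i], receptor$y[i], receptor$z[i],
            receptor$element[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  if (!is.null(charges_path)) {
    write.csv(data.frame(atom_serial = receptor$serial,
                         charge = receptor$charge,
                         radius = receptor$radius),
              charges_path, row.names = FALSE)
  }
  invisible(path)
}
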