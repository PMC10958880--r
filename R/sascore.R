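# Synthetic accessibility score: fragment-frequency contribution minus a
# structural complexity penalty, mapped monotonically into [1, 10]
# (1 = trivially accessible, 10 = very hard). The fragment frequency table is
# built at first use from a bundled reference set of common drug-like and
# fragment SMILES, so scores are fully reproducible offline; a user table can
# be supplied instead.

.sascore_env <- new.env(parent = emptyenv())

#' Fragment frequency table for the synthetic accessibility score
#'
#' Counts of circular atom-environment identifiers (radius 2) over a
#' reference compound set. Frequent environments are "easy" chemistry; rare
#' or unseen ones are penalised.
#'
#' @param path Optional two-column CSV (`fragment_id`, `count`) to use
#'   instead of the bundled table.
#' @return Named numeric vector of counts keyed by environment identifier.
#' @export
default_fragment_table <- function(path = NULL) {
  if (!is.null(path)) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    return(setNames(as.numeric(df[[2]]), as.character(df[[1]])))
  }
  if (is.null(.sascore_env$table)) {
    ref <- system.file("extdata", "reference_smiles.txt", package = "hittriage")
    smiles <- readLines(ref, warn = FALSE)
    smiles <- trimws(sub("#.*$", "", smiles))
    smiles <- smiles[nzchar(smiles)]
    counts <- new.env(parent = emptyenv())
    for (s in smiles) {
      sdf <- smiles_to_sdf_one(s)
      if (is.null(sdf)) next
      ids <- as.character(morgan_identifiers(mol_graph(sdf), radius = 2))
      for (id in ids) {
        counts[[id]] <- (counts[[id]] %||% 0) + 1
      }
    }
    ids <- ls(counts)
    .sascore_env$table <- setNames(
      vapply(ids, function(i) counts[[i]], numeric(1)), ids)
  }
  .sascore_env$table
}

#' Synthetic accessibility score
#'
#' Adds `fragment_score`, `complexity_penalty` and `sascore` columns. The
#' fragment score is the mean log10 relative frequency of each atom
#' environment (radius 0-2) under the fragment table, clipped to \[-4, 4\];
#' the complexity penalty sums size, ring-fusion, stereo-centre and
#' macrocycle terms. `sascore` rescales
#' `fragment_score - complexity_penalty` monotonically (decreasing) into
#' \[1, 10\].
#'
#' @param mols A molecule table.
#' @param fragment_table From [default_fragment_table()].
#' @return `mols` with the three score columns added.
#' @export
compute_sascore <- function(mols, fragment_table = default_fragment_table()) {
  n <- nrow(mols)
  fs <- cp <- sc <- rep(NA_real_, n)
  if (n) {
    sdfset <- mols_as_sdfset(mols)
    for (i in seq_len(n)) {
      sdf <- sdfset$list[[i]]
      if (is.null(sdf)) next
      b <- sascore_one(sdf, mols$smiles[i], fragment_table)
      fs[i] <- b$fragment_score
      cp[i] <- b$complexity_penalty
      sc[i] <- b$sascore
    }
  }
  mols$fragment_score <- fs
  mols$complexity_penalty <- cp
  mols$sascore <- sc
  mols
}

sascore_one <- function(sdf, smiles, fragment_table) {
  g <- mol_graph(sdf)
  n_heavy <- sum(g$heavy)
  if (n_heavy == 0) abort("cannot score an empty molecule")
  ids <- as.character(morgan_identifiers(g, radius = 2))
  med <- stats::median(fragment_table)
  contrib <- vapply(ids, function(id) {
    f <- fragment_table[id]
    if (is.na(f)) -4 else max(-4, min(4, log10(f / med)))
  }, numeric(1))
  fragment_score <- mean(contrib)

  size_penalty <- n_heavy^1.005 - n_heavy
  # ring fusion: extra independent cycles beyond one per ring system
  rb <- sum(g$ring_bond)
  ra <- sum(g$ring_atom)
  fusion_penalty <- log10(max(rb - ra, 0) + 1)
  stereo_penalty <- log10(count_stereo_marks(smiles) + 1)
  macro_penalty <- if (has_macrocycle(g)) log10(2) else 0
  complexity_penalty <- 0.25 * size_penalty + fusion_penalty +
    stereo_penalty + macro_penalty

  raw <- fragment_score - complexity_penalty
  # monotone decreasing map of raw onto [1, 10]; anchors chosen so that
  # frequent simple chemistry (raw ~ 1.5) lands near 1.5 and heavily
  # penalised rare chemistry (raw ~ -6) saturates near 10
  lo <- -6; hi <- 1.5
  scaled <- 1 + 9 * (hi - raw) / (hi - lo)
  sascore <- min(10, max(1, scaled))
  list(fragment_score = fragment_score,
       complexity_penalty = complexity_penalty,
       sascore = sascore)
}

count_stereo_marks <- function(smiles) {
  if (is.na(smiles)) return(0L)
  # each stereocentre appears as one @ or @@ token inside brackets
  lengths(regmatches(smiles, gregexpr("@+", smiles)))
}

has_macrocycle <- function(g) {
  if (!any(g$ring_bond)) return(FALSE)
  # components of the ring-bond subgraph that are single cycles of size > 8
  ring_adj <- vector("list", g$n)
  rb <- which(g$ring_bond)
  for (k in rb) {
    i <- g$bonds[k, 1]; j <- g$bonds[k, 2]
    ring_adj[[i]] <- c(ring_adj[[i]], j)
    ring_adj[[j]] <- c(ring_adj[[j]], i)
  }
  keep <- lengths(ring_adj) > 0
  comp <- graph_components(keep, ring_adj)
  for (cid in unique(stats::na.omit(comp))) {
    atoms <- which(!is.na(comp) & comp == cid)
    nb <- sum(vapply(rb, function(k) {
      all(g$bonds[k, 1:2] %in% atoms)
    }, logical(1)))
    if (length(atoms) > 8 && nb == length(atoms)) return(TRUE)
  }
  FALSE
}
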