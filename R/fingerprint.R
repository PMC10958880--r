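# Circular (Morgan / extended-connectivity) fingerprints, diameter 6
# (radius 3), folded to 2048 bits. Implemented directly on the molecular
# graph with deterministic integer hashing so bit assignments are stable
# across platforms and sessions.

.hash_mod <- 2147483647  # 2^31 - 1; keeps products inside exact doubles

hash_fold <- function(values) {
  h <- 17
  for (v in values) h <- (h * 1000003 + (v %% .hash_mod)) %% .hash_mod
  h
}

#' Circular fingerprint of a molecule
#'
#' ECFP-style iterative-neighbourhood fingerprint. The initial atom invariant
#' hashes (atomic number, heavy degree, attached hydrogens, formal charge,
#' ring membership); each iteration folds in the sorted (bond order,
#' neighbour invariant) list. Environment identifiers from radii
#' `0..radius` set bits modulo `nbits`.
#'
#' @param sdf A `ChemmineR::SDF` object (or a `mol_graph()` list).
#' @param radius Neighbourhood radius; 3 corresponds to diameter-6 ECFP.
#' @param nbits Folded length.
#' @return Integer vector of 0/1 of length `nbits`.
#' @export
morgan_fingerprint <- function(sdf, radius = 3, nbits = 2048) {
  g <- if (is.list(sdf) && !is.null(sdf$adj)) sdf else mol_graph(sdf)
  ids <- morgan_identifiers(g, radius)
  fp <- integer(nbits)
  if (length(ids)) fp[(ids %% nbits) + 1L] <- 1L
  fp
}

# All environment identifiers (heavy atoms only), radii 0..radius.
morgan_identifiers <- function(g, radius) {
  heavy_idx <- which(g$heavy)
  if (!length(heavy_idx)) return(integer(0))
  inv <- vapply(seq_len(g$n), function(i) {
    z <- .element_z[g$element[i]]
    if (is.na(z)) z <- 99 + hash_fold(utf8ToInt(g$element[i]))
    heavy_deg <- sum(g$element[g$adj[[i]]] != "H")
    hash_fold(c(z, heavy_deg, g$n_h[i], g$charge[i] + 10,
                as.integer(g$ring_atom[i])))
  }, numeric(1))
  all_ids <- inv[heavy_idx]
  # bond orders between atom pairs for the update step
  border <- list()
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      i <- g$bonds[k, 1]; j <- g$bonds[k, 2]
      border[[paste(i, j)]] <- g$bonds[k, 3]
      border[[paste(j, i)]] <- g$bonds[k, 3]
    }
  }
  cur <- inv
  for (r in seq_len(radius)) {
    nxt <- cur
    for (i in heavy_idx) {
      nbs <- g$adj[[i]]
      nbs <- nbs[g$element[nbs] != "H"]
      if (length(nbs)) {
        pairs <- vapply(nbs, function(j) {
          bo <- border[[paste(i, j)]] %||% 1L
          bo * .hash_mod + cur[j]  # order pairs by (bond order, invariant)
        }, numeric(1))
        ord <- order(pairs)
        flat <- as.vector(rbind(
          vapply(nbs[ord], function(j) border[[paste(i, j)]] %||% 1L, numeric(1)),
          cur[nbs[ord]]
        ))
        nxt[i] <- hash_fold(c(r, cur[i], flat))
      } else {
        nxt[i] <- hash_fold(c(r, cur[i]))
      }
    }
    cur <- nxt
    all_ids <- c(all_ids, cur[heavy_idx])
  }
  all_ids
}

#' Tanimoto similarity between two bit vectors
#'
#' @param a,b Integer 0/1 vectors of equal length.
#' @return Tanimoto coefficient in \[0, 1\]; two all-zero vectors give 1
#'   (identical emptiness), one all-zero against a non-empty vector gives 0.
#' @export
tanimoto <- function(a, b) {
  ab <- sum(a & b)
  den <- sum(a | b)
  if (den == 0) return(1)
  ab / den
}

# Row-wise Tanimoto distance matrix for a 0/1 matrix (n x bits).
tanimoto_distance_matrix <- function(fp) {
  fp <- as.matrix(fp)
  storage.mode(fp) <- "numeric"
  inter <- tcrossprod(fp)
  ones <- rowSums(fp)
  uni <- outer(ones, ones, "+") - inter
  sim <- ifelse(uni == 0, 1, inter / pmax(uni, 1e-300))
  d <- 1 - sim
  diag(d) <- 0
  d
}
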