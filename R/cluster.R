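# Maximum-dissimilarity clustering of scaffold fingerprints with a distance
# cap. Distance is 1 - Tanimoto on the scaffold fingerprint (not the whole
# molecule). The greedy farthest-point variant is fixed with explicit
# tie-breaking so results are deterministic and testable:
#   * first center: the point with the largest summed distance to all
#     others; ties broken by lowest record_id;
#   * repeatedly promote the point farthest from its nearest center while
#     that distance exceeds max_distance (ties: lowest record_id);
#   * assign every point to its nearest center (ties: earlier center).
# Acyclic molecules (empty scaffold) are pooled into the NO_SCAFFOLD
# pseudo-cluster and excluded from center selection.

# Greedy maximum-dissimilarity center selection on a distance matrix over
# (unique) points with multiplicities. `rep_id` supplies the deterministic
# tie-break key (lowest id wins); assignment ties go to the earlier center.
greedy_maxdis <- function(dmat, rep_id, mult = rep(1L, nrow(dmat)),
                          max_distance = 0.625) {
  sums <- as.vector(dmat %*% mult)
  cand <- which(sums == max(sums))
  first <- cand[order(rep_id[cand])][1]
  center_u <- first
  nearest <- dmat[, first]
  repeat {
    far <- max(nearest)
    if (far <= max_distance) break
    cand <- which(nearest == far)
    nxt <- cand[order(rep_id[cand])][1]
    center_u <- c(center_u, nxt)
    nearest <- pmin(nearest, dmat[, nxt])
  }
  dcent <- dmat[, center_u, drop = FALSE]
  assign_u <- apply(dcent, 1, which.min)   # first minimum = earlier center
  list(center_u = center_u, assign_u = assign_u)
}

#' Cluster molecules by scaffold fingerprint
#'
#' @param mols A molecule table with a `scaffold_smiles` column (see
#'   [murcko_assembly()]).
#' @param max_distance Distance cap, default 0.625.
#' @param nbits,radius Fingerprint parameters (diameter-6 circular, 2048
#'   bits by default).
#' @return A `scaffold_clustering` object: list with `centers` (record ids
#'   in selection order), `membership` (tibble `record_id`, `cluster_id`),
#'   `cluster_sizes` (named integer), `max_distance`. Supports [tidy()] and
#'   [glance()].
#' @export
cluster_scaffolds <- function(mols, max_distance = 0.625, nbits = 2048,
                              radius = 3) {
  stopifnot(nrow(mols) >= 1)
  if (!"scaffold_smiles" %in% names(mols)) {
    abort("run murcko_assembly() first: scaffold_smiles column is required")
  }
  scaf <- mols$scaffold_smiles
  scaf[is.na(scaf)] <- ""
  ids <- mols$record_id
  has_scaf <- nzchar(scaf)

  membership <- tibble::tibble(record_id = ids,
                               cluster_id = rep(NA_character_, length(ids)))
  membership$cluster_id[!has_scaf] <- "NO_SCAFFOLD"
  centers <- character(0)

  if (any(has_scaf)) {
    sub_ids <- ids[has_scaf]
    sub_scaf <- scaf[has_scaf]
    uniq <- sort(unique(sub_scaf))
    fp <- scaffold_fingerprint(uniq, nbits = nbits, radius = radius)
    dmat <- tanimoto_distance_matrix(fp)        # unique-scaffold distances
    u_of <- match(sub_scaf, uniq)
    mult <- tabulate(u_of, length(uniq))
    # representative (lowest) record id per unique scaffold, for tie-breaks
    rep_id <- vapply(seq_along(uniq), function(u) {
      min(sub_ids[u_of == u])
    }, character(1))
    g <- greedy_maxdis(dmat, rep_id, mult, max_distance)
    centers <- rep_id[g$center_u]
    cluster_names <- sprintf("C%03d", seq_along(g$center_u))
    membership$cluster_id[has_scaf] <- cluster_names[g$assign_u[u_of]]
  }

  sizes <- table(membership$cluster_id)
  structure(
    list(centers = centers,
         membership = membership,
         cluster_sizes = setNames(as.integer(sizes), names(sizes)),
         max_distance = max_distance,
         nbits = nbits, radius = radius),
    class = "scaffold_clustering"
  )
}

#' @export
print.scaffold_clustering <- function(x, ...) {
  cat("Scaffold clustering:", length(x$centers), "clusters",
      if ("NO_SCAFFOLD" %in% names(x$cluster_sizes)) "(+ NO_SCAFFOLD)" else "",
      "over", nrow(x$membership), "molecules; max distance",
      x$max_distance, "\n")
  invisible(x)
}

#' Annotate molecules with cluster id and size
#'
#' Sets the `cluster_id` and `cluster_size` columns (SDF tags `CLUSTER_ID`,
#' `CLUSTER_SIZE`) from a clustering. Re-annotation is idempotent.
#'
#' @param mols A molecule table.
#' @param clustering From [cluster_scaffolds()].
#' @return `mols` with both columns set.
#' @export
annotate_clusters <- function(mols, clustering) {
  idx <- match(mols$record_id, clustering$membership$record_id)
  if (anyNA(idx)) abort("clustering does not cover all records")
  mols$cluster_id <- clustering$membership$cluster_id[idx]
  mols$cluster_size <-
    unname(clustering$cluster_sizes[mols$cluster_id])
  mols
}

#' @export
tidy.scaffold_clustering <- function(x, ...) {
  m <- x$membership
  m$cluster_size <- unname(x$cluster_sizes[m$cluster_id])
  m$is_center <- m$record_id %in% x$centers
  m
}

#' @export
glance.scaffold_clustering <- function(x, ...) {
  tibble::tibble(
    n_molecules = nrow(x$membership),
    n_clusters = length(x$centers),
    n_no_scaffold = sum(x$membership$cluster_id == "NO_SCAFFOLD"),
    max_distance = x$max_distance
  )
}
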