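# 2-D chemical-space map of two compound collections: descriptor matrix
# (four standardized chemical-physical properties + diameter-6 circular
# fingerprint), seeded t-SNE embedding normalized to the unit square, and
# buffered-disc overlap geometry computed by rasterization.

#' Descriptor matrix for chemical-space embedding
#'
#' Per record: the four chemical-physical properties (standardized to zero
#' mean, unit variance; zero-variance columns are zeroed) concatenated with
#' the 2048-bit circular fingerprint left binary. Width is always
#' `4 + nbits`.
#'
#' @param mols A molecule table; property columns are computed on the fly
#'   when absent.
#' @param nbits,radius Fingerprint parameters.
#' @return Numeric matrix, one row per record.
#' @export
compute_descriptors <- function(mols, nbits = 2048, radius = 3) {
  needed <- c("molecular_weight", "alogp", "psa", "n_rotatable_bonds")
  if (!all(needed %in% names(mols))) mols <- compute_properties(mols)
  props <- as.matrix(mols[, needed])
  props <- apply(props, 2, function(v) {
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    s <- sd(v)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  })
  if (nrow(mols) == 1) props <- matrix(0, 1, 4)  # single row: centred to 0
  sdfset <- mols_as_sdfset(mols)
  fp <- t(vapply(seq_len(nrow(mols)), function(i) {
    sdf <- sdfset$list[[i]]
    if (is.null(sdf)) return(integer(nbits))
    morgan_fingerprint(sdf, radius = radius, nbits = nbits)
  }, integer(nbits)))
  out <- cbind(props, fp)
  rownames(out) <- mols$record_id
  out
}

#' Embed descriptors into the unit square with t-SNE
#'
#' Seeded, deterministic embedding; coordinates are min-max normalized so
#' all points lie in the unit square. Inputs wider than 50 columns are first
#' reduced by PCA for speed.
#'
#' @param X Descriptor matrix from [compute_descriptors()] (rows >= 5).
#' @param labels Collection label per row (e.g. `"A"` / `"B"`).
#' @param seed RNG seed for the embedding.
#' @param radius Buffer radius in normalized units, default 0.02.
#' @param perplexity,n_iter t-SNE controls.
#' @return An `embedding_map`: list with `points` (tibble `record_id, x, y,
#'   label`), `radius`, `seed`. Supports [tidy()] and [autoplot()].
#' @export
embed_2d <- function(X, labels, seed = 7, radius = 0.02, perplexity = 30,
                     n_iter = 400) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 5, length(labels) == nrow(X))
  if (radius <= 0) abort("radius must be positive")
  Xr <- X
  if (ncol(X) > 50) {
    keep <- apply(X, 2, function(v) sd(v) > 0)
    pc <- prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
    k <- min(50, ncol(pc$x))
    Xr <- pc$x[, seq_len(k), drop = FALSE]
  }
  Y <- tsne_exact(Xr, perplexity = perplexity, n_iter = n_iter, seed = seed)
  rng_x <- range(Y[, 1]); rng_y <- range(Y[, 2])
  span_x <- max(rng_x[2] - rng_x[1], 1e-12)
  span_y <- max(rng_y[2] - rng_y[1], 1e-12)
  pts <- tibble::tibble(
    record_id = rownames(X) %||% as.character(seq_len(nrow(X))),
    x = (Y[, 1] - rng_x[1]) / span_x,
    y = (Y[, 2] - rng_y[1]) / span_y,
    label = as.character(labels)
  )
  structure(list(points = pts, radius = radius, seed = seed),
            class = "embedding_map")
}

#' @export
print.embedding_map <- function(x, ...) {
  cat("Chemical-space embedding:", nrow(x$points), "points,",
      length(unique(x$points$label)), "collections, buffer radius",
      x$radius, "\n")
  invisible(x)
}

#' @export
tidy.embedding_map <- function(x, ...) x$points

#' Buffered-disc overlap of two embedded collections
#'
#' Each point is buffered to a disc of the map's radius; discs are unioned
#' per collection and areas (in unit-square units) of each union and their
#' intersection are computed by rasterization.
#'
#' @param map An `embedding_map` with exactly two labels.
#' @param resolution Raster resolution per axis, default 1024.
#' @param radius Override the map's buffer radius.
#' @return An `overlap_stats` list: `area_a`, `area_b`, `area_overlap`,
#'   `overlap_fraction_a`, `overlap_fraction_b`, plus the labels.
#' @export
buffered_overlap <- function(map, resolution = 1024, radius = NULL) {
  radius <- radius %||% map$radius
  if (radius <= 0) abort("radius must be positive")
  labs <- sort(unique(map$points$label))
  if (length(labs) != 2) abort("overlap needs exactly two collections")
  ga <- disc_union_mask(map$points[map$points$label == labs[1], ],
                        radius, resolution)
  gb <- disc_union_mask(map$points[map$points$label == labs[2], ],
                        radius, resolution)
  cell <- ((1 + 4 * radius) / (resolution - 1))^2
  area_a <- sum(ga) * cell
  area_b <- sum(gb) * cell
  area_ab <- sum(ga & gb) * cell
  structure(list(
    label_a = labs[1], label_b = labs[2],
    area_a = area_a, area_b = area_b, area_overlap = area_ab,
    overlap_fraction_a = if (area_a > 0) area_ab / area_a else 0,
    overlap_fraction_b = if (area_b > 0) area_ab / area_b else 0,
    resolution = resolution, radius = radius
  ), class = "overlap_stats")
}

# logical raster of the union of discs; canvas pads the unit square by 2r so
# buffers of edge points are not clipped
disc_union_mask <- function(pts, radius, resolution) {
  lo <- -2 * radius; hi <- 1 + 2 * radius
  ax <- seq(lo, hi, length.out = resolution)
  mask <- matrix(FALSE, resolution, resolution)
  step <- (hi - lo) / (resolution - 1)
  for (k in seq_len(nrow(pts))) {
    cx <- pts$x[k]; cy <- pts$y[k]
    i0 <- max(1, floor((cx - radius - lo) / step) + 1)
    i1 <- min(resolution, ceiling((cx + radius - lo) / step) + 1)
    j0 <- max(1, floor((cy - radius - lo) / step) + 1)
    j1 <- min(resolution, ceiling((cy + radius - lo) / step) + 1)
    if (i0 > i1 || j0 > j1) next
    xs <- ax[i0:i1]; ys <- ax[j0:j1]
    d2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
    mask[i0:i1, j0:j1] <- mask[i0:i1, j0:j1] | (d2 <= radius^2)
  }
  mask
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf(
    "Buffered overlap (r = %g): area %s = %.5f, area %s = %.5f, overlap = %.5f\n",
    x$radius, x$label_a, x$area_a, x$label_b, x$area_b, x$area_overlap))
  invisible(x)
}

#' @export
glance.overlap_stats <- function(x, ...) {
  tibble::tibble(area_a = x$area_a, area_b = x$area_b,
                 area_overlap = x$area_overlap,
                 overlap_fraction_a = x$overlap_fraction_a,
                 overlap_fraction_b = x$overlap_fraction_b,
                 radius = x$radius, resolution = x$resolution)
}
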