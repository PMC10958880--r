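# Shape + pharmacophore-feature similarity ("Tanimoto Combo" surrogate).
# Rigid alignment by centering and principal axes (all four proper axis-flip
# combinations, best kept, no torsional sampling); shape overlap from
# Gaussian atom volumes sampled on a 0.4 A grid; feature Tanimoto from
# Gaussian overlap of typed pharmacophore points (donor, acceptor, aromatic,
# hydrophobe, cation, anion). Absolute values differ from the commercial
# shape tool, so the combo cutoff is configurable everywhere it is used.

.gauss_p <- 2.7  # Grant-Pickup amplitude; alpha chosen to match vdW volume

gauss_alpha <- function(radius) {
  pi * (3 * .gauss_p / (4 * sqrt(pi)))^(2 / 3) / radius^2
}

conformer_atoms <- function(sdf) {
  g <- mol_graph(sdf)
  keep <- g$heavy
  xyz <- g$xyz[keep, , drop = FALSE]
  if (nrow(xyz) == 0 || all(abs(xyz) < 1e-9)) {
    abort("record has no usable conformer; provide 3-D input")
  }
  rad <- unname(.vdw_radius[g$element[keep]])
  rad[is.na(rad)] <- 1.7
  list(xyz = xyz, radius = rad, graph = g, heavy_idx = which(keep))
}

# Gaussian product-form density on a grid covering both molecules.
shape_grid_density <- function(xyz, radius, grid) {
  dens <- rep(1, nrow(grid))
  alpha <- gauss_alpha(radius)
  for (i in seq_len(nrow(xyz))) {
    d2 <- (grid[, 1] - xyz[i, 1])^2 + (grid[, 2] - xyz[i, 2])^2 +
      (grid[, 3] - xyz[i, 3])^2
    dens <- dens * (1 - .gauss_p * exp(-alpha[i] * d2))
  }
  1 - pmax(dens, -1)  # product form keeps density within [0, 1] range-ish
}

shape_overlap_volumes <- function(A, B, spacing = 0.4) {
  lo <- pmin(apply(A$xyz, 2, min), apply(B$xyz, 2, min)) - 3
  hi <- pmax(apply(A$xyz, 2, max), apply(B$xyz, 2, max)) + 3
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  grid <- as.matrix(expand.grid(gx, gy, gz))
  da <- shape_grid_density(A$xyz, A$radius, grid)
  db <- shape_grid_density(B$xyz, B$radius, grid)
  cell <- spacing^3
  list(vaa = sum(da * da) * cell, vbb = sum(db * db) * cell,
       vab = sum(da * db) * cell)
}

# Align candidate onto query (principal frames + best proper flip by shape
# overlap) and return both atom sets in the common frame.
aligned_pair <- function(query, candidate, spacing = 0.4) {
  A <- conformer_atoms(get_sdf(query))
  B0 <- conformer_atoms(get_sdf(candidate))
  A$xyz <- apply_frame(A$xyz, principal_frame(A))
  B0$xyz <- apply_frame(B0$xyz, principal_frame(B0))
  best <- NULL; best_st <- -Inf
  for (Fm in .proper_flips) {
    B <- B0; B$xyz <- B0$xyz %*% Fm
    v <- shape_overlap_volumes(A, B, spacing = spacing)
    st <- v$vab / (v$vaa + v$vbb - v$vab)
    if (st > best_st) { best_st <- st; best <- B }
  }
  list(A = A, B = best, shape_tanimoto = best_st)
}

# Monte-Carlo counterpart of the grid integral (used as an oracle in the
# test-suite; exported because it is occasionally useful for calibration).
#' @rdname shape_feature_similarity
#' @param n_points Number of Monte-Carlo samples.
#' @param seed RNG seed for the sampling.
#' @export
shape_tanimoto_mc <- function(query, candidate, n_points = 1e6, seed = 1) {
  al <- aligned_pair(query, candidate)
  A <- al$A; B <- al$B
  lo <- pmin(apply(A$xyz, 2, min), apply(B$xyz, 2, min)) - 3
  hi <- pmax(apply(A$xyz, 2, max), apply(B$xyz, 2, max)) + 3
  set.seed(seed)
  pts <- cbind(runif(n_points, lo[1], hi[1]), runif(n_points, lo[2], hi[2]),
               runif(n_points, lo[3], hi[3]))
  vol <- prod(hi - lo)
  da <- shape_grid_density(A$xyz, A$radius, pts)
  db <- shape_grid_density(B$xyz, B$radius, pts)
  vaa <- mean(da * da) * vol; vbb <- mean(db * db) * vol
  vab <- mean(da * db) * vol
  vab / (vaa + vbb - vab)
}

# principal-axes frame: center at volume-weighted centroid, rotate onto
# eigenvectors of the weighted coordinate covariance
principal_frame <- function(atoms) {
  w <- atoms$radius^3
  ctr <- colSums(atoms$xyz * w) / sum(w)
  xc <- sweep(atoms$xyz, 2, ctr)
  cv <- crossprod(xc * sqrt(w)) / sum(w)
  ev <- eigen(cv, symmetric = TRUE)
  R <- ev$vectors
  if (det(R) < 0) R[, 3] <- -R[, 3]
  list(center = ctr, rotation = R)
}

apply_frame <- function(xyz, frame) {
  sweep(xyz, 2, frame$center) %*% frame$rotation
}

.proper_flips <- list(diag(3), diag(c(1, -1, -1)), diag(c(-1, 1, -1)),
                      diag(c(-1, -1, 1)))

get_sdf <- function(x) {
  if (inherits(x, "SDF")) return(x)
  if (is.data.frame(x) && "mol" %in% names(x)) {
    if (nrow(x) != 1) abort("expected a single molecule row")
    x <- x$mol[[1]]
    if (is.null(x)) abort("record has no conformer; provide 3-D input")
    return(x)
  }
  abort("cannot extract an SDF structure; provide 3-D input")
}

#' Shape + pharmacophore similarity between two conformers
#'
#' Returns the shape Tanimoto, the typed-feature Tanimoto, and their sum
#' (the combo score, range 0-2). Both molecules must carry 3-D conformers;
#' the candidate is rigidly aligned onto the query before scoring.
#'
#' @param query,candidate Single-row molecule tables or `ChemmineR::SDF`
#'   objects with 3-D coordinates.
#' @param spacing Grid spacing in Angstrom for the shape integral.
#' @return One-row tibble `query_id, candidate_id, shape_tanimoto,
#'   feature_tanimoto, combo`.
#' @export
shape_feature_similarity <- function(query, candidate, spacing = 0.4) {
  qid <- if (is.data.frame(query)) query$record_id[1] else "query"
  cid <- if (is.data.frame(candidate)) candidate$record_id[1] else "candidate"
  al <- aligned_pair(query, candidate, spacing = spacing)
  ft <- feature_tanimoto(al$A, al$B)
  tibble::tibble(query_id = qid, candidate_id = cid,
                 shape_tanimoto = al$shape_tanimoto, feature_tanimoto = ft,
                 combo = al$shape_tanimoto + ft)
}

# typed pharmacophore points (coordinates already in the aligned frame)
pharmacophore_points <- function(atoms) {
  g <- atoms$graph
  idx <- atoms$heavy_idx
  xyz <- atoms$xyz
  pts <- list()
  addp <- function(type, coord) {
    pts[[length(pts) + 1]] <<- c(list(type = type), as.list(coord))
  }
  for (k in seq_along(idx)) {
    i <- idx[k]
    el <- g$element[i]
    if (el %in% c("N", "O")) {
      if (g$n_h[i] > 0) addp("donor", xyz[k, ])
      if (g$charge[i] <= 0) addp("acceptor", xyz[k, ])
    }
    if (el == "C") {
      nb <- g$adj[[i]]
      if (all(g$element[nb] %in% c("C", "H"))) addp("hydrophobe", xyz[k, ])
    }
    if (g$charge[i] > 0) addp("cation", xyz[k, ])
    if (g$charge[i] < 0) addp("anion", xyz[k, ])
  }
  # aromatic ring centroids: rings whose atoms are all flagged aromatic by
  # simple criterion (ring of 5-6 atoms, all sp2 C/N/O/S)
  arom <- aromatic_ring_centroids(g, idx, xyz)
  for (ctr in arom) addp("aromatic", ctr)
  if (!length(pts)) {
    return(tibble::tibble(type = character(0), x = numeric(0),
                          y = numeric(0), z = numeric(0)))
  }
  dplyr::bind_rows(lapply(pts, function(p) {
    tibble::tibble(type = p$type, x = p[[2]], y = p[[3]], z = p[[4]])
  }))
}

aromatic_ring_centroids <- function(g, heavy_idx, xyz) {
  if (!any(g$ring_bond)) return(list())
  # cycles of the ring subgraph limited to isolated 5/6-rings and fused pairs
  rings <- simple_rings(g, max_size = 6)
  out <- list()
  for (r in rings) {
    if (length(r) < 5) next
    els <- g$element[r]
    if (!all(els %in% c("C", "N", "O", "S"))) next
    # sp2-ness proxy: every ring atom participates in a double/aromatic bond
    # or is O/S/N
    sp2 <- vapply(r, function(i) {
      if (g$element[i] %in% c("O", "S", "N")) return(TRUE)
      any(vapply(seq_len(nrow(g$bonds)), function(k) {
        (g$bonds[k, 1] == i || g$bonds[k, 2] == i) && g$bonds[k, 3] >= 2
      }, logical(1)))
    }, logical(1))
    if (!all(sp2)) next
    pos <- xyz[match(r, heavy_idx), , drop = FALSE]
    if (anyNA(pos)) next
    out[[length(out) + 1]] <- colMeans(pos)
  }
  out
}

# minimal cycle enumeration: BFS shortest cycle through each ring bond
simple_rings <- function(g, max_size = 6) {
  rb <- which(g$ring_bond)
  seen <- character(0)
  rings <- list()
  for (k in rb) {
    i <- g$bonds[k, 1]; j <- g$bonds[k, 2]
    path <- bfs_path(g, i, j, forbid_edge = k)
    if (is.null(path) || length(path) > max_size) next
    key <- paste(sort(path), collapse = "-")
    if (key %in% seen) next
    seen <- c(seen, key)
    rings[[length(rings) + 1]] <- path
  }
  rings
}

bfs_path <- function(g, from, to, forbid_edge) {
  prev <- rep(NA_integer_, g$n)
  prev[from] <- from
  queue <- from
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    if (v == to) break
    for (w in g$adj[[v]]) {
      ek <- which((g$bonds[, 1] == v & g$bonds[, 2] == w) |
                    (g$bonds[, 1] == w & g$bonds[, 2] == v))[1]
      if (ek == forbid_edge) next
      if (!is.na(prev[w])) next
      prev[w] <- v
      queue <- c(queue, w)
    }
  }
  if (is.na(prev[to])) return(NULL)
  path <- to
  while (path[1] != from) path <- c(prev[path[1]], path)
  path
}

# Gaussian overlap of typed feature points; sigma 1 A. Types are pooled
# ROCS-style: combo of per-type overlaps over the union of self-overlaps.
feature_tanimoto <- function(A, B) {
  fa <- pharmacophore_points(A)
  fb <- pharmacophore_points(B)
  if (!nrow(fa) && !nrow(fb)) return(1)
  if (!nrow(fa) || !nrow(fb)) return(0)
  types <- union(fa$type, fb$type)
  alpha <- 1 / (2 * 1.0^2)
  voverlap <- function(p, q) {
    if (!nrow(p) || !nrow(q)) return(0)
    d2 <- outer(p$x, q$x, "-")^2 + outer(p$y, q$y, "-")^2 +
      outer(p$z, q$z, "-")^2
    sum((pi / (2 * alpha))^1.5 * exp(-alpha * d2 / 2))
  }
  vab <- vaa <- vbb <- 0
  for (t in types) {
    pa <- fa[fa$type == t, ]; pb <- fb[fb$type == t, ]
    vab <- vab + voverlap(pa, pb)
    vaa <- vaa + voverlap(pa, pa)
    vbb <- vbb + voverlap(pb, pb)
  }
  if (vaa + vbb - vab <= 0) return(0)
  vab / (vaa + vbb - vab)
}
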