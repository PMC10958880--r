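# Virtual-hit chemotype (SAR) enrichment: per-cluster Fisher tests against
# the hit annotation, a dynamic binding-score cutoff sweep targeting 100-200
# diverse hit scaffolds, and per-cluster top-score scaffold selection.

#' Build the 2x2 contingency table for one cluster
#'
#' Layout (fixed): `a` = hits in the cluster, `b` = hits outside, `c` =
#' non-hits in the cluster, `d` = non-hits outside; `n = a + b + c + d`.
#'
#' @param mols Molecule table with `cluster_id` and a logical hit vector.
#' @param cluster_id The cluster to tabulate (must be non-empty and present).
#' @param hit A logical vector along `mols` (or the name of a logical
#'   column, default `"is_virtual_hit"`).
#' @return A named list `a, b, c, d, n`.
#' @export
build_contingency <- function(mols, cluster_id, hit = "is_virtual_hit") {
  if (!"cluster_id" %in% names(mols)) abort("cluster_id column required")
  if (is.character(hit) && length(hit) == 1) {
    if (!hit %in% names(mols)) abort(paste0("no column ", hit))
    hit <- mols[[hit]]
  }
  stopifnot(is.logical(hit), length(hit) == nrow(mols))
  if (is.na(cluster_id) || !nzchar(cluster_id)) {
    abort("cluster_id must be a non-empty string")
  }
  inc <- mols$cluster_id == cluster_id
  if (!any(inc)) abort(paste0("cluster not present: ", cluster_id))
  hit[is.na(hit)] <- FALSE
  a <- sum(hit & inc); b <- sum(hit & !inc)
  c <- sum(!hit & inc); d <- sum(!hit & !inc)
  list(a = a, b = b, c = c, d = d, n = a + b + c + d)
}

#' Per-cluster enrichment of virtual hits
#'
#' Runs Fisher's exact test for every cluster (the `NO_SCAFFOLD`
#' pseudo-cluster is excluded by default). The hit predicate is
#' `delta_g <= dg_cutoff` AND `sas_pass` AND `qed_pass`; set
#' `dg_only = TRUE` to sweep on the binding score alone.
#'
#' @param mols Molecule table with `cluster_id`, `delta_g`, `sas_pass`,
#'   `qed_pass` columns.
#' @param dg_cutoff Binding-score cutoff defining hits (inclusive).
#' @param alpha Significance level; a cluster is enriched iff
#'   `p_value <= alpha`.
#' @param alternative Passed to [fisher_exact()].
#' @param include_no_scaffold Include the `NO_SCAFFOLD` pool?
#' @param dg_only Ignore `sas_pass` / `qed_pass` in the hit predicate.
#' @param p_adjust `"none"` (default, raw p as published) or `"BH"`.
#' @return Tibble `cluster_id, a, b, c, d, n, p_value, enriched`, sorted by
#'   `p_value` then `cluster_id`.
#' @export
enrich_clusters <- function(mols, dg_cutoff = -6, alpha = 0.05,
                            alternative = "greater",
                            include_no_scaffold = FALSE,
                            dg_only = FALSE, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (!all(c("cluster_id", "delta_g") %in% names(mols))) {
    abort("cluster_id and delta_g columns required")
  }
  hit <- mols$delta_g <= dg_cutoff
  if (!dg_only) {
    sas_ok <- if ("sas_pass" %in% names(mols)) mols$sas_pass else TRUE
    qed_ok <- if ("qed_pass" %in% names(mols)) mols$qed_pass else TRUE
    hit <- hit & sas_ok & qed_ok
  }
  hit[is.na(hit)] <- FALSE
  clusters <- sort(unique(mols$cluster_id))
  clusters <- clusters[!is.na(clusters)]
  if (!include_no_scaffold) clusters <- setdiff(clusters, "NO_SCAFFOLD")
  # margin counts per cluster, vectorised
  res <- purrr::map_dfr(clusters, function(cl) {
    inc <- mols$cluster_id == cl
    a <- sum(hit & inc); b <- sum(hit & !inc)
    cc <- sum(!hit & inc); d <- sum(!hit & !inc)
    tibble::tibble(cluster_id = cl, a = a, b = b, c = cc, d = d,
                   n = a + b + cc + d)
  })
  if (!nrow(res)) {
    res$p_value <- numeric(0); res$enriched <- logical(0)
    return(res)
  }
  res$p_value <- purrr::pmap_dbl(res[, c("a", "b", "c", "d")],
                                 function(a, b, c, d) {
                                   fisher_exact(a, b, c, d,
                                                alternative = alternative)
                                 })
  if (p_adjust == "BH") res$p_value <- stats::p.adjust(res$p_value, "BH")
  res$enriched <- res$p_value <= alpha
  dplyr::arrange(res, .data$p_value, .data$cluster_id)
}

#' Select top-scoring scaffold representatives from enriched clusters
#'
#' For each enriched cluster, the `per_cluster` members with the lowest
#' (best) binding score; score ties resolved by lexicographically lowest
#' `record_id`. Clusters smaller than `per_cluster` contribute all their
#' members.
#'
#' @param enrichment Result of [enrich_clusters()].
#' @param mols The molecule table the enrichment was computed on.
#' @param per_cluster Representatives per cluster, default 1.
#' @return Character vector of record ids.
#' @export
select_scaffolds <- function(enrichment, mols, per_cluster = 1) {
  enriched <- enrichment$cluster_id[enrichment$enriched]
  if (!length(enriched)) return(character(0))
  out <- character(0)
  for (cl in enriched) {
    sub <- mols[mols$cluster_id == cl & !is.na(mols$delta_g), ]
    if (!nrow(sub)) next
    ord <- order(sub$delta_g, sub$record_id)
    out <- c(out, sub$record_id[ord][seq_len(min(per_cluster, nrow(sub)))])
  }
  out
}

#' Sweep the binding-score cutoff to reach a scaffold-count target
#'
#' Starting from `start` (default -6 kcal/mol) and stepping by `step`
#' (default -0.1), runs the enrichment at each cutoff and counts the
#' selected scaffolds; stops at the first cutoff whose scaffold count falls
#' inside `target` (default 100-200). If no cutoff lands in the target band
#' within `max_steps`, the cutoff minimising the distance to the band is
#' chosen and the result flagged.
#'
#' @param mols Scored, clustered molecule table.
#' @param start,step,max_steps Sweep grid.
#' @param target Length-2 inclusive band for the scaffold count.
#' @param alpha,alternative,dg_only,per_cluster Passed through to
#'   [enrich_clusters()] / [select_scaffolds()].
#' @return A `dg_sweep` object: `trace` tibble (`cutoff, n_hits,
#'   n_enriched_clusters, n_scaffolds`), `chosen_cutoff`, `scaffolds`
#'   (record ids at the chosen cutoff), `in_target`, `flagged`. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
sweep_cutoff <- function(mols, start = -6, step = -0.1,
                         target = c(100, 200), max_steps = 100,
                         alpha = 0.05, alternative = "greater",
                         dg_only = FALSE, per_cluster = 1) {
  stopifnot(step < 0, length(target) == 2, target[1] <= target[2])
  if (!any(mols$delta_g <= start, na.rm = TRUE)) {
    out <- structure(list(
      trace = tibble::tibble(cutoff = numeric(0), n_hits = integer(0),
                             n_enriched_clusters = integer(0),
                             n_scaffolds = integer(0)),
      chosen_cutoff = NA_real_, scaffolds = character(0),
      in_target = FALSE, flagged = TRUE, target = target),
      class = "dg_sweep")
    return(out)
  }
  trace <- list(); chosen <- NULL; scaffolds <- character(0)
  in_target <- FALSE
  sel_by_step <- list()
  for (k in seq_len(max_steps)) {
    cutoff <- start + (k - 1) * step
    enr <- enrich_clusters(mols, dg_cutoff = cutoff, alpha = alpha,
                           alternative = alternative, dg_only = dg_only)
    sel <- select_scaffolds(enr, mols, per_cluster = per_cluster)
    hit <- mols$delta_g <= cutoff
    if (!dg_only) {
      if ("sas_pass" %in% names(mols)) hit <- hit & mols$sas_pass
      if ("qed_pass" %in% names(mols)) hit <- hit & mols$qed_pass
    }
    trace[[k]] <- tibble::tibble(
      cutoff = cutoff, n_hits = sum(hit, na.rm = TRUE),
      n_enriched_clusters = sum(enr$enriched),
      n_scaffolds = length(sel))
    sel_by_step[[k]] <- sel
    if (length(sel) >= target[1] && length(sel) <= target[2]) {
      chosen <- cutoff; scaffolds <- sel; in_target <- TRUE
      break
    }
  }
  trace <- dplyr::bind_rows(trace)
  if (is.null(chosen)) {
    dist <- pmax(target[1] - trace$n_scaffolds,
                 trace$n_scaffolds - target[2], 0)
    k <- which.min(dist)  # first minimiser: earliest (least negative) cutoff
    chosen <- trace$cutoff[k]
    scaffolds <- sel_by_step[[k]]
  }
  structure(list(trace = trace, chosen_cutoff = chosen,
                 scaffolds = scaffolds, in_target = in_target,
                 flagged = !in_target, target = target),
            class = "dg_sweep")
}

#' @export
print.dg_sweep <- function(x, ...) {
  cat("Binding-score cutoff sweep:", nrow(x$trace), "steps; chosen cutoff",
      format(x$chosen_cutoff), "->", length(x$scaffolds), "scaffolds",
      if (x$flagged) "(flagged: target band not reached)" else "", "\n")
  invisible(x)
}

#' @export
tidy.dg_sweep <- function(x, ...) x$trace

#' @export
glance.dg_sweep <- function(x, ...) {
  tibble::tibble(chosen_cutoff = x$chosen_cutoff,
                 n_scaffolds = length(x$scaffolds),
                 in_target = x$in_target, flagged = x$flagged,
                 target_low = x$target[1], target_high = x$target[2])
}
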