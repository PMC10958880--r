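# Library searching: map top scaffolds into a compound library by combined
# shape + feature similarity, rescore survivors with the binding score, and
# apply pluggable availability / QC / solubility predicates in declared
# order with per-stage counts.

#' Search a library by Tanimoto-Combo similarity to query scaffolds
#'
#' Computes [shape_feature_similarity()] for every (query, candidate) pair,
#' keeps pairs with `combo >= combo_cutoff`, and retains the best-scoring
#' query per candidate (alternates are dropped but counted). Output ordering
#' is deterministic: combo descending, then candidate id.
#'
#' @param scaffolds Molecule table of query scaffolds with 3-D conformers.
#' @param library Molecule table of library compounds with 3-D conformers.
#' @param combo_cutoff Minimum combo score, default 1.0.
#' @param spacing Shape-grid spacing (A).
#' @return Tibble `query_id, candidate_id, shape_tanimoto,
#'   feature_tanimoto, combo`.
#' @export
search_library <- function(scaffolds, library, combo_cutoff = 1.0,
                           spacing = 0.4) {
  res <- list()
  for (i in seq_len(nrow(scaffolds))) {
    q <- scaffolds[i, ]
    for (j in seq_len(nrow(library))) {
      sim <- shape_feature_similarity(q, library[j, ], spacing = spacing)
      if (sim$combo >= combo_cutoff) res[[length(res) + 1]] <- sim
    }
  }
  if (!length(res)) {
    return(tibble::tibble(query_id = character(0), candidate_id = character(0),
                          shape_tanimoto = numeric(0),
                          feature_tanimoto = numeric(0), combo = numeric(0)))
  }
  out <- dplyr::bind_rows(res)
  out <- out |>
    dplyr::group_by(.data$candidate_id) |>
    dplyr::slice_max(.data$combo, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$combo), .data$candidate_id)
  out
}

#' Rescore similarity matches and build the focused set
#'
#' Candidates are scored with the binding scorer (or their external
#' `delta_g` tag is used when present), filtered at `dg_cutoff`, then passed
#' through each named predicate in declared order. Predicates are Boolean
#' functions of the candidate table (or names of logical columns, e.g.
#' Boolean SDF tags `quantity_ok`, `qc_ok`, `solubility_ok`).
#'
#' @param candidates Molecule table (typically the library rows matched by
#'   [search_library()]).
#' @param receptor Optional receptor for [score_binding()]; omit when
#'   `delta_g` is already present.
#' @param dg_cutoff Inclusive binding-score cutoff (use the sweep's chosen
#'   cutoff).
#' @param predicates Named list of predicate functions
#'   (`function(tbl) logical`) and/or character names of logical columns.
#' @param params Binding parameters, see [binding_params()].
#' @return A `focused_set` object with the per-stage counts `n_library`,
#'   `n_past_combo`, `n_past_dg`, `n_past_predicates`, the per-predicate
#'   counts, and `selected_ids`.
#' @export
rescore_and_filter <- function(candidates, receptor = NULL, dg_cutoff = -6,
                               predicates = list(),
                               params = binding_params()) {
  n0 <- nrow(candidates)
  if (!"delta_g" %in% names(candidates) || anyNA(candidates$delta_g)) {
    if (is.null(receptor)) {
      if (!"delta_g" %in% names(candidates)) {
        abort("no delta_g scores and no receptor to compute them")
      }
    } else {
      candidates <- score_binding(candidates, receptor, params)
    }
  }
  keep <- !is.na(candidates$delta_g) & candidates$delta_g <= dg_cutoff
  cur <- candidates[keep, ]
  n_dg <- nrow(cur)
  stage_counts <- c(n_library = n0, n_past_combo = n0, n_past_dg = n_dg)
  pred_counts <- integer(0)
  for (k in seq_along(predicates)) {
    p <- predicates[[k]]
    nm <- names(predicates)[k] %||% paste0("predicate_", k)
    ok <- if (is.character(p)) {
      v <- cur[[p]]
      if (is.null(v)) rep(FALSE, nrow(cur)) else !is.na(v) & as.logical(v)
    } else {
      as.logical(p(cur))
    }
    ok[is.na(ok)] <- FALSE
    cur <- cur[ok, ]
    pred_counts[nm] <- nrow(cur)
  }
  structure(list(
    stage_counts = stage_counts,
    predicate_counts = pred_counts,
    n_past_predicates = nrow(cur),
    selected_ids = cur$record_id,
    dg_cutoff = dg_cutoff
  ), class = "focused_set")
}

#' @export
print.focused_set <- function(x, ...) {
  cat("Focused set:", x$stage_counts["n_library"], "->",
      x$stage_counts["n_past_dg"], "past dG cutoff", format(x$dg_cutoff),
      "->", x$n_past_predicates, "past predicates\n")
  invisible(x)
}

#' @export
glance.focused_set <- function(x, ...) {
  tibble::tibble(
    n_library = unname(x$stage_counts["n_library"]),
    n_past_combo = unname(x$stage_counts["n_past_combo"]),
    n_past_dg = unname(x$stage_counts["n_past_dg"]),
    n_past_predicates = x$n_past_predicates,
    dg_cutoff = x$dg_cutoff
  )
}

#' @export
tidy.focused_set <- function(x, ...) {
  tibble::tibble(record_id = x$selected_ids)
}
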