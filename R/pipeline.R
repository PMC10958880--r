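# End-to-end orchestration: validation -> property filter -> secondary
# scores -> scaffold clustering of the property-filter survivors -> cutoff
# sweep + enrichment -> scaffold selection -> optional library search, with
# per-stage counts and a machine-readable report.

#' Pipeline configuration
#'
#' Every published threshold is a named key defaulting to its printed value.
#'
#' @param input Input molecule table, or a path readable by
#'   [read_molecules()].
#' @param receptor Optional receptor (object or PDB path) for the binding
#'   scorer; omit when scores arrive in the `GBVI_WSA_dG` tag.
#' @param thresholds [property_thresholds()].
#' @param cutoffs [hit_cutoffs()].
#' @param max_distance Scaffold clustering distance cap.
#' @param dg_start,dg_step,scaffold_target,alpha Sweep and enrichment
#'   controls.
#' @param library Optional library table (or path) for the search stage.
#' @param combo_cutoff Similarity cutoff for the search stage.
#' @param predicates Named predicate list for [rescore_and_filter()].
#' @param out_dir Optional directory for per-stage SDF/CSV/JSON outputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, receptor = NULL,
                            thresholds = property_thresholds(),
                            cutoffs = hit_cutoffs(),
                            max_distance = 0.625,
                            dg_start = -6, dg_step = -0.1,
                            scaffold_target = c(100, 200),
                            alpha = 0.05,
                            library = NULL, combo_cutoff = 1.0,
                            predicates = list(),
                            out_dir = NULL) {
  structure(list(input = input, receptor = receptor,
                 thresholds = thresholds, cutoffs = cutoffs,
                 max_distance = max_distance, dg_start = dg_start,
                 dg_step = dg_step, scaffold_target = scaffold_target,
                 alpha = alpha, library = library,
                 combo_cutoff = combo_cutoff, predicates = predicates,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full triage pipeline
#'
#' Stages, in order: read/validate, chemical-physical property filter,
#' SAscore + QED, binding score (external tag wins), Bemis-Murcko
#' clustering of the property-filter survivors, binding-score cutoff sweep
#' with per-cluster Fisher enrichment, top-scaffold selection, and (when a
#' library is configured) similarity search plus focused-set filtering.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report`: `stage_counts` (named, in stage order),
#'   `chosen_dg_cutoff`, `sweep`, `enrichment`, `scaffold_ids`, `mols` (the
#'   fully annotated table), optionally `search` and `focused`. Supports
#'   [glance()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  mols <- config$input
  if (is.character(mols)) mols <- read_molecules(mols)
  counts <- c(input = nrow(mols) + nrow(mol_rejects(mols)))

  vr <- validate_molecules(mols)
  mols <- mols[vr$is_valid, ]
  counts["valid"] <- nrow(mols)

  if (!all(c("molecular_weight", "alogp", "psa", "n_rotatable_bonds") %in%
             names(mols))) {
    mols <- compute_properties(mols)
  }
  mols <- apply_property_filter(mols, config$thresholds)
  surv <- mols[mols$pf_pass, ]
  counts["property_pass"] <- nrow(surv)

  if (!"sascore" %in% names(surv)) surv <- compute_sascore(surv)
  if (!"qed" %in% names(surv)) surv <- compute_qed(surv)
  if (!"delta_g" %in% names(surv)) surv$delta_g <- NA_real_
  if (anyNA(surv$delta_g)) {
    receptor <- config$receptor
    if (is.character(receptor)) receptor <- read_receptor(receptor)
    if (!is.null(receptor)) surv <- score_binding(surv, receptor)
  }
  surv <- apply_hit_filters(surv, config$cutoffs)
  counts["virtual_hits"] <- sum(surv$is_virtual_hit, na.rm = TRUE)

  if (!"cluster_id" %in% names(surv)) {
    if (!"scaffold_smiles" %in% names(surv)) surv <- murcko_assembly(surv)
    clustering <- cluster_scaffolds(surv, max_distance = config$max_distance)
    surv <- annotate_clusters(surv, clustering)
  } else {
    clustering <- NULL
  }
  counts["clusters"] <- length(setdiff(unique(surv$cluster_id), "NO_SCAFFOLD"))

  sweep <- sweep_cutoff(surv, start = config$dg_start, step = config$dg_step,
                        target = config$scaffold_target, alpha = config$alpha)
  enr <- enrich_clusters(surv, dg_cutoff = sweep$chosen_cutoff %||% config$dg_start,
                         alpha = config$alpha)
  counts["enriched_clusters"] <- sum(enr$enriched)
  counts["scaffolds"] <- length(sweep$scaffolds)

  report <- list(stage_counts = counts,
                 chosen_dg_cutoff = sweep$chosen_cutoff,
                 sweep = sweep, enrichment = enr,
                 scaffold_ids = sweep$scaffolds,
                 clustering = clustering, mols = surv)

  if (!is.null(config$library)) {
    lib <- config$library
    if (is.character(lib)) lib <- read_molecules(lib)
    queries <- surv[surv$record_id %in% sweep$scaffolds, ]
    hits <- search_library(queries, lib, combo_cutoff = config$combo_cutoff)
    counts["library_matches"] <- nrow(hits)
    cand <- lib[lib$record_id %in% hits$candidate_id, ]
    receptor <- config$receptor
    if (is.character(receptor)) receptor <- read_receptor(receptor)
    focused <- rescore_and_filter(cand, receptor = receptor,
                                  dg_cutoff = sweep$chosen_cutoff %||% config$dg_start,
                                  predicates = config$predicates)
    counts["focused_set"] <- focused$n_past_predicates
    report$search <- hits
    report$focused <- focused
    report$stage_counts <- counts
  }

  if (!is.null(config$out_dir)) write_pipeline_outputs(report, config)
  class(report) <- "pipeline_report"
  report
}

write_pipeline_outputs <- function(report, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_molecules(report$mols, file.path(config$out_dir, "annotated.sdf"))
  write.csv(report$enrichment,
            file.path(config$out_dir, "enrichment.csv"), row.names = FALSE)
  write.csv(tidy(report$sweep),
            file.path(config$out_dir, "sweep_trace.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(stage_counts = as.list(report$stage_counts),
         chosen_dg_cutoff = report$chosen_dg_cutoff,
         scaffold_ids = report$scaffold_ids),
    file.path(config$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  for (nm in names(x$stage_counts)) {
    cat(sprintf("  %-18s %d\n", nm, x$stage_counts[[nm]]))
  }
  cat("  chosen dG cutoff  ", format(x$chosen_dg_cutoff), "\n")
  invisible(x)
}

#' @export
glance.pipeline_report <- function(x, ...) {
  out <- tibble::as_tibble(as.list(x$stage_counts))
  out$chosen_dg_cutoff <- x$chosen_dg_cutoff
  out
}

#' Hit rate as a percentage
#'
#' `100 * hits / tested`, rounded half-up to 3 decimals -- the convention
#' used in screening summaries (7 actives among 2029 tested prints as
#' 0.345).
#'
#' @param hits,tested Non-negative counts, `tested > 0`, `hits <= tested`.
#' @return Percentage rounded to 3 decimals.
#' @export
#' @examples
#' hit_rate(7, 2029)
hit_rate <- function(hits, tested) {
  stopifnot(tested > 0, hits >= 0, hits <= tested)
  floor(100 * hits / tested * 1000 + 0.5) / 1000
}
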