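# Hit calling: the three secondary-filter cutoffs, all inclusive exactly as
# published (SAscore <= 4, QED >= 0.5, binding dG <= -6 kcal/mol).

#' Hit-calling cutoffs
#'
#' @param sas_max Maximum SAscore (inclusive), default 4.
#' @param qed_min Minimum QED (inclusive), default 0.5.
#' @param dg_max Maximum binding score in kcal/mol (inclusive; more negative
#'   is better), default -6.
#' @return Named list of cutoffs.
#' @export
hit_cutoffs <- function(sas_max = 4, qed_min = 0.5, dg_max = -6) {
  list(sas_max = sas_max, qed_min = qed_min, dg_max = dg_max)
}

#' Apply the hit-calling filters
#'
#' Adds `sas_pass`, `qed_pass`, `dg_pass` and `is_virtual_hit` (SDF tag
#' `HIT`) columns; a virtual hit passes all three inclusive comparisons.
#' Missing scores fail closed.
#'
#' @param mols A molecule table with `sascore`, `qed` and `delta_g` columns.
#' @param cutoffs From [hit_cutoffs()].
#' @return `mols` with the four Boolean columns added.
#' @export
#' @examples
#' m <- tibble::tibble(record_id = "x", smiles = "C",
#'                     sascore = 4, qed = 0.5, delta_g = -6)
#' apply_hit_filters(as_mol_tbl(m))$is_virtual_hit
apply_hit_filters <- function(mols, cutoffs = hit_cutoffs()) {
  needed <- c("sascore", "qed", "delta_g")
  missing_cols <- setdiff(needed, names(mols))
  if (length(missing_cols)) {
    abort(paste0("missing score columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  sas_pass <- mols$sascore <= cutoffs$sas_max
  qed_pass <- mols$qed >= cutoffs$qed_min
  dg_pass <- mols$delta_g <= cutoffs$dg_max
  sas_pass[is.na(sas_pass)] <- FALSE
  qed_pass[is.na(qed_pass)] <- FALSE
  dg_pass[is.na(dg_pass)] <- FALSE
  mols$sas_pass <- sas_pass
  mols$qed_pass <- qed_pass
  mols$dg_pass <- dg_pass
  mols$is_virtual_hit <- sas_pass & qed_pass & dg_pass
  mols
}
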