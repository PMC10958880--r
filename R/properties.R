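# Chemical-physical properties and the primary filter.
#
# Molecular weight, atomic-contribution logP and topological PSA are
# delegated to OpenBabel (ChemmineR::propOB); rotatable bonds are counted on
# the molecular graph with the definition: non-ring single bonds between two
# non-terminal heavy atoms, amide C-N excluded (the SMARTS equivalent is
# [!D1;!$(C(=O)N)]-!@[!D1;!$(N(C=O))] restricted to the C(=O)-N bond itself).

#' Compute the four chemical-physical properties
#'
#' Adds `molecular_weight` (Da), `alogp` (atomic-contribution octanol-water
#' logP), `psa` (topological polar surface area, A^2) and
#' `n_rotatable_bonds` to the molecule table. Descriptors that cannot be
#' computed are left `NA`; the primary filter fails closed on them.
#'
#' @param mols A molecule table.
#' @return `mols` with the four property columns added (overwritten if
#'   already present).
#' @export
#' @examples
#' mols <- mol_tbl("m1", "CCO", list(smiles_to_sdf_one("CCO")))
#' compute_properties(mols)[, c("molecular_weight", "psa", "n_rotatable_bonds")]
compute_properties <- function(mols) {
  n <- nrow(mols)
  mw <- alogp <- psa <- rep(NA_real_, n)
  rotb <- rep(NA_integer_, n)
  if (n) {
    sdfset <- mols_as_sdfset(mols)
    ok <- sdfset$keep
    if (any(ok)) {
      props <- tryCatch(ob_props(sdfset$list), error = function(e) NULL)
      if (!is.null(props) && nrow(props) == sum(ok)) {
        mw[ok] <- props$MW
        alogp[ok] <- props$logP
        psa[ok] <- props$TPSA
      }
      rotb[ok] <- vapply(which(ok), function(i) {
        count_rotatable_bonds(mol_graph(sdfset$list[[i]]))
      }, integer(1))
    }
  }
  mols$molecular_weight <- mw
  mols$alogp <- alogp
  mols$psa <- psa
  mols$n_rotatable_bonds <- rotb
  mols
}

# Assemble the per-record SDF list (parsing from SMILES when the structure
# column is absent).
mols_as_sdfset <- function(mols) {
  lst <- purrr::map(seq_len(nrow(mols)), function(i) {
    sdf <- if ("mol" %in% names(mols)) mols$mol[[i]] else NULL
    if (is.null(sdf)) sdf <- smiles_to_sdf_one(mols$smiles[i])
    sdf
  })
  keep <- !vapply(lst, is.null, logical(1))
  list(list = lst, keep = keep)
}

# Serialize a list of SDF objects (NULLs skipped) and apply an OpenBabel
# callback per molecule; returns the list of results, aligned to the
# non-NULL entries.
ob_for_each <- function(sdf_list, fn) {
  keep <- !vapply(sdf_list, is.null, logical(1))
  if (!any(keep)) return(list())
  blocks <- vapply(which(keep), function(i) {
    paste(c(sdf_block_lines(sdf_list[[i]], paste0("m", i)), "$$$$"),
          collapse = "\n")
  }, character(1))
  txt <- paste0(paste(blocks, collapse = "\n"), "\n")
  res <- list()
  ChemmineOB::forEachMol("SDF", txt, function(mol) {
    res[[length(res) + 1]] <<- fn(mol)
  })
  res
}

# OpenBabel descriptor table for a list of SDF objects; rows aligned to the
# non-NULL entries.
ob_props <- function(sdf_list) {
  res <- ob_for_each(sdf_list, ChemmineOB::prop_OB)
  if (!length(res)) return(NULL)
  dplyr::bind_rows(res)
}

# SMARTS match counts per molecule (non-NULL entries).
ob_smarts_count <- function(sdf_list, pattern, unique_matches = TRUE) {
  res <- tryCatch(
    ob_for_each(sdf_list, function(mol) {
      ChemmineOB::smartsSearch_OB(mol, pattern,
                                  uniqueMatches = unique_matches)
    }),
    error = function(e) NULL
  )
  if (is.null(res)) return(rep(0, sum(!vapply(sdf_list, is.null, logical(1)))))
  as.numeric(unlist(res))
}

count_rotatable_bonds <- function(g) {
  if (!nrow(g$bonds)) return(0L)
  heavy_deg <- vapply(seq_len(g$n), function(i) {
    sum(g$element[g$adj[[i]]] != "H")
  }, integer(1))
  cnt <- 0L
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds[k, 1]; j <- g$bonds[k, 2]
    if (g$bonds[k, 3] != 1L) next            # single bonds only
    if (g$ring_bond[k]) next                 # non-ring only
    if (g$element[i] == "H" || g$element[j] == "H") next
    if (heavy_deg[i] < 2L || heavy_deg[j] < 2L) next  # non-terminal
    if (is_amide_cn(g, i, j)) next           # amide C-N excluded
    cnt <- cnt + 1L
  }
  cnt
}

is_amide_cn <- function(g, i, j) {
  check <- function(cc, nn) {
    if (g$element[cc] != "C" || g$element[nn] != "N") return(FALSE)
    # carbon double-bonded to oxygen?
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds[k, 1]; b <- g$bonds[k, 2]
      if (g$bonds[k, 3] == 2L &&
          ((a == cc && g$element[b] == "O") ||
           (b == cc && g$element[a] == "O"))) return(TRUE)
    }
    FALSE
  }
  check(i, j) || check(j, i)
}

#' Primary-filter thresholds
#'
#' Defaults follow the published protocol: molecular weight no greater than
#' 800 Da, AlogP between -1 and 7 (read as inclusive; configurable since the
#' protocol wording is ambiguous), PSA strictly less than 125 A^2, and fewer
#' than 12 rotatable bonds.
#'
#' @param mw_max,alogp_min,alogp_max,psa_max,rotb_max Numeric cutoffs.
#' @param alogp_inclusive Should the AlogP bounds be inclusive? Default TRUE.
#' @return A named list of thresholds.
#' @export
property_thresholds <- function(mw_max = 800, alogp_min = -1, alogp_max = 7,
                                psa_max = 125, rotb_max = 12,
                                alogp_inclusive = TRUE) {
  stopifnot(alogp_min < alogp_max)
  list(mw_max = mw_max, alogp_min = alogp_min, alogp_max = alogp_max,
       psa_max = psa_max, rotb_max = rotb_max,
       alogp_inclusive = alogp_inclusive)
}

#' Apply the primary chemical-physical property filter
#'
#' Adds the Boolean `pf_pass` column (SDF tag `PF_PASS`): `TRUE` iff
#' `molecular_weight <= mw_max`, `alogp` within `[alogp_min, alogp_max]`,
#' `psa < psa_max` and `n_rotatable_bonds < rotb_max`. The decision depends
#' only on the property profile; records with missing properties fail
#' closed.
#'
#' @param mols A molecule table carrying the four property columns (call
#'   [compute_properties()] first, or supply them directly).
#' @param thresholds A list from [property_thresholds()].
#' @return `mols` with `pf_pass` added.
#' @export
apply_property_filter <- function(mols, thresholds = property_thresholds()) {
  needed <- c("molecular_weight", "alogp", "psa", "n_rotatable_bonds")
  missing_cols <- setdiff(needed, names(mols))
  if (length(missing_cols)) {
    abort(paste0("missing property columns: ",
                 paste(missing_cols, collapse = ", "),
                 " (run compute_properties() first)"))
  }
  th <- thresholds
  in_alogp <- if (isTRUE(th$alogp_inclusive)) {
    mols$alogp >= th$alogp_min & mols$alogp <= th$alogp_max
  } else {
    mols$alogp > th$alogp_min & mols$alogp < th$alogp_max
  }
  pass <- mols$molecular_weight <= th$mw_max &
    in_alogp &
    mols$psa < th$psa_max &
    mols$n_rotatable_bonds < th$rotb_max
  pass[is.na(pass)] <- FALSE  # uncomputable descriptor fails closed
  mols$pf_pass <- pass
  mols
}
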