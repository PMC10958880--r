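# Molecule tables: every stage of the pipeline operates on a tibble with one
# row per molecule. Mandatory columns are `record_id` (unique character key)
# and `smiles` (canonical); `mol` is an optional list-column of ChemmineR SDF
# objects carrying connectivity and (when present) a 3-D conformer. All other
# columns are annotations that round-trip through SDF data items.

# Mapping between tidy column names and the exact SDF tag names written to
# data blocks. Tag names are part of the file contract and are bit-exact.
.tag_map <- c(
  pf_pass         = "PF_PASS",
  sascore         = "SAS",
  qed             = "QED",
  delta_g         = "GBVI_WSA_dG",
  is_virtual_hit  = "HIT",
  cluster_id      = "CLUSTER_ID",
  cluster_size    = "CLUSTER_SIZE",
  scaffold_smiles = "SCAFFOLD_SMILES"
)

#' Construct a molecule table
#'
#' Builds the tibble representation used throughout the pipeline from parallel
#' vectors of identifiers and SMILES, with an optional list of ChemmineR
#' `SDF` objects carrying conformers.
#'
#' @param record_id Character vector of unique record identifiers.
#' @param smiles Character vector of SMILES strings (canonicalised on entry).
#' @param mol Optional list of `ChemmineR::SDF` objects, one per record (or
#'   `NULL` entries for records without structures).
#' @param ... Additional annotation columns (recycled per tibble rules).
#' @param canonicalize Canonicalise the SMILES on entry (default) so
#'   duplicate detection is stable under one convention.
#' @return A tibble with class `mol_tbl` prepended.
#' @export
mol_tbl <- function(record_id, smiles, mol = NULL, ..., canonicalize = TRUE) {
  record_id <- as.character(record_id)
  if (anyDuplicated(record_id)) {
    abort("record_id values must be unique within a molecule table")
  }
  smiles <- as.character(smiles)
  if (canonicalize) {
    can <- canonical_smiles(smiles)
    smiles <- ifelse(is.na(can), smiles, can)
  }
  out <- tibble::tibble(record_id = record_id, smiles = smiles, ...)
  if (!is.null(mol)) out$mol <- mol
  as_mol_tbl(out)
}

#' @export
as_mol_tbl <- function(x) {
  stopifnot(is.data.frame(x), "record_id" %in% names(x))
  x <- tibble::as_tibble(x)
  class(x) <- unique(c("mol_tbl", class(x)))
  x
}

#' Rejected entries attached to a molecule table
#'
#' Unparseable entries encountered by [read_molecules()] are never silently
#' dropped; they are recorded in a rejects tibble (index, raw identifier,
#' reason) attached to the returned table.
#'
#' @param mols A molecule table.
#' @return A tibble with columns `index`, `id`, `reason` (zero rows if all
#'   entries parsed).
#' @export
mol_rejects <- function(mols) {
  attr(mols, "rejects") %||%
    tibble::tibble(index = integer(), id = character(), reason = character())
}

`mol_rejects<-` <- function(mols, value) {
  attr(mols, "rejects") <- value
  mols
}

# Canonical SMILES via OpenBabel; one convention fixed at load time so that
# duplicate detection and scaffold identity are stable across the package.
canonical_smiles <- function(smiles) {
  smiles <- as.character(smiles)
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(out)
  res <- vapply(smiles[ok], function(s) {
    ans <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", source = s),
      error = function(e) NA_character_
    )
    if (is.na(ans)) return(NA_character_)
    strsplit(ans, "[\t\n ]")[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  out[ok] <- res
  out
}

#' Parse a single SMILES into a ChemmineR SDF object
#'
#' 2-D coordinates are generated; returns `NULL` (never throws) when the
#' SMILES cannot be parsed, so malformed entries are isolated instead of
#' failing a batch.
#'
#' @param s A SMILES string.
#' @return A `ChemmineR::SDF` object or `NULL`.
#' @export
smiles_to_sdf_one <- function(s) {
  txt <- tryCatch(ChemmineOB::convertFormat("SMI", "SDF", source = s),
                  error = function(e) NA_character_)
  if (is.na(txt) || !nzchar(txt)) return(NULL)
  parse_molblock(strsplit(txt, "\n")[[1]])
}

# Minimal V2000 molblock parser building a ChemmineR SDF object directly.
# Handles the zero-bond and single-atom cases the stock reader rejects, and
# folds M CHG lines back into the atom-line charge-code column so formal
# charges survive. Returns NULL on any structural problem.
parse_molblock <- function(lines) {
  out <- tryCatch({
    if (length(lines) < 4) return(NULL)
    counts <- lines[4]
    natoms <- as.integer(substr(counts, 1, 3))
    nbonds <- as.integer(substr(counts, 4, 6))
    if (is.na(natoms) || natoms < 1 || is.na(nbonds)) return(NULL)
    if (length(lines) < 4 + natoms + nbonds) return(NULL)
    atom_lines <- lines[5:(4 + natoms)]
    sym <- trimws(substr(atom_lines, 32, 34))
    if (any(!grepl("^[A-Za-z*]{1,3}$", sym))) return(NULL)
    # column layout mirrors ChemmineR's own atomblock (15 numeric fields,
    # x/y/z then the MDL integer fields; position 5 is the charge code)
    ab <- matrix(0, nrow = natoms, ncol = 15,
                 dimnames = list(paste0(sym, "_", seq_len(natoms)),
                                 c("C1", "C2", "C3", paste0("C", 5:16))))
    ab[, 1] <- as.numeric(substr(atom_lines, 1, 10))
    ab[, 2] <- as.numeric(substr(atom_lines, 11, 20))
    ab[, 3] <- as.numeric(substr(atom_lines, 21, 30))
    cc <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
    cc[is.na(cc)] <- 0L
    ab[, 5] <- cc
    if (anyNA(ab[, 1:3])) return(NULL)
    bb <- matrix(0L, nrow = max(nbonds, 0), ncol = 7,
                 dimnames = list(NULL, paste0("C", seq_len(7))))
    if (nbonds > 0) {
      bond_lines <- lines[(5 + natoms):(4 + natoms + nbonds)]
      bb[, 1] <- as.integer(substr(bond_lines, 1, 3))
      bb[, 2] <- as.integer(substr(bond_lines, 4, 6))
      bb[, 3] <- as.integer(substr(bond_lines, 7, 9))
      if (anyNA(bb[, 1:3]) || any(bb[, 1] < 1) || any(bb[, 2] < 1) ||
          any(bb[, 1] > natoms) || any(bb[, 2] > natoms)) return(NULL)
    }
    for (ln in grep("^M  CHG", lines, value = TRUE)) {
      flds <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))),
                                  "[ ]+")[[1]])
      npair <- flds[1]
      for (p in seq_len(npair)) {
        at <- flds[2 * p]; q <- flds[2 * p + 1]
        if (!is.na(at) && at >= 1 && at <= natoms && !is.na(q) && q != 0) {
          ab[at, 5] <- 4L - q
        }
      }
    }
    methods::new("SDF",
                 header = c(Molecule_Name = trimws(lines[1]),
                            Source = "  hittriage", Comment = "",
                            Counts_Line = counts),
                 atomblock = ab, bondblock = bb, datablock = character(0))
  }, error = function(e) NULL)
  out
}

# SDF data items of one entry's text block: named character vector.
parse_data_items <- function(lines) {
  idx <- grep("^>\\s*<", lines)
  out <- character(0)
  for (i in idx) {
    tag <- sub("^>\\s*<([^>]+)>.*$", "\\1", lines[i])
    j <- i + 1
    vals <- character(0)
    while (j <= length(lines) && nzchar(trimws(lines[j])) &&
           !grepl("^\\$\\$\\$\\$", lines[j]) && !grepl("^>\\s*<", lines[j])) {
      vals <- c(vals, lines[j])
      j <- j + 1
    }
    out[tag] <- paste(vals, collapse = "\n")
  }
  out
}

heavy_atom_count <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  sum(!grepl("^H_", rownames(ab)))
}
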