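# SDF / SMILES input and output. V2000 SDF is read and written through
# ChemmineR; V3000 input is converted to V2000 via OpenBabel before parsing.

#' Read molecules from SDF or SMILES into a molecule table
#'
#' Reads every entry of the file in order. Entries that fail to parse are
#' never silently dropped: they are recorded in a rejects tibble retrievable
#' with [mol_rejects()]. SDF data items become annotation columns; the tag
#' names `PF_PASS`, `SAS`, `QED`, `GBVI_WSA_dG`, `HIT`, `CLUSTER_ID`,
#' `CLUSTER_SIZE`, `SCAFFOLD_SMILES` map to the package's tidy column names
#' and are parsed to the appropriate types.
#'
#' @param path Path to an existing file.
#' @param format `"sdf"`, `"smiles"` or `"auto"` (infer from extension;
#'   `.smi`/`.smiles`/`.txt` are SMILES, everything else SDF).
#' @return A `mol_tbl` tibble with columns `record_id`, `smiles`, `mol`
#'   (list of `ChemmineR::SDF`), plus one column per data tag; rejects are
#'   attached as an attribute.
#' @export
#' @examples
#' f <- tempfile(fileext = ".smi")
#' writeLines(c("c1ccccc1 benzene", "CCO ethanol"), f)
#' mols <- read_molecules(f)
#' mols$smiles
read_molecules <- function(path, format = c("auto", "sdf", "smiles")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("input file does not exist: ", path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.(smi|smiles|txt|ism)$", path, ignore.case = TRUE))
      "smiles" else "sdf"
  }
  if (format == "smiles") read_smiles_file(path) else read_sdf_file(path)
}

read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  records <- list(); rejects <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    smi <- parts[1]
    id <- if (length(parts) > 1) parts[2] else sprintf("mol_%04d", i)
    can <- canonical_smiles(smi)
    sdf <- if (!is.na(can)) smiles_to_sdf_one(smi) else NULL
    if (is.na(can) || is.null(sdf)) {
      rejects[[length(rejects) + 1]] <-
        tibble::tibble(index = i, id = id, reason = "parse")
    } else {
      records[[length(records) + 1]] <-
        tibble::tibble(record_id = id, smiles = can, mol = list(sdf))
    }
  }
  finish_read(records, rejects)
}

read_sdf_file <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (any(grepl("V3000", txt, fixed = TRUE))) {
    txt <- strsplit(ChemmineOB::convertFormat(
      "SDF", "SDF", source = paste0(paste(txt, collapse = "\n"), "\n")),
      "\n")[[1]]
  }
  # split into molblocks on $$$$ delimiters
  ends <- grep("^\\$\\$\\$\\$", txt)
  if (!length(ends)) {
    if (!any(nzchar(trimws(txt)))) return(finish_read(list(), list()))
    ends <- length(txt)  # single entry without terminator
  }
  starts <- c(1L, head(ends, -1) + 1L)
  records <- list(); rejects <- list()
  for (k in seq_along(starts)) {
    block <- txt[starts[k]:ends[k]]
    if (!any(nzchar(trimws(block)))) next
    name <- trimws(block[1])
    id <- if (nzchar(name)) name else sprintf("mol_%04d", k)
    parsed <- tryCatch({
      sdf <- parse_molblock(block)
      if (is.null(sdf)) stop("malformed connection table")
      can <- sdf_to_canonical_smiles(block)
      if (is.na(can)) stop("unparseable structure")
      list(sdf = sdf, smiles = can)
    }, error = function(e) NULL)
    if (is.null(parsed)) {
      rejects[[length(rejects) + 1]] <-
        tibble::tibble(index = k, id = id, reason = "parse")
      next
    }
    ann <- parse_datablock(parse_data_items(block))
    records[[length(records) + 1]] <- dplyr::bind_cols(
      tibble::tibble(record_id = id, smiles = parsed$smiles,
                     mol = list(parsed$sdf)),
      ann
    )
  }
  finish_read(records, rejects)
}

sdf_to_canonical_smiles <- function(block_lines) {
  src <- paste0(paste(block_lines, collapse = "\n"), "\n")
  out <- tryCatch(ChemmineOB::convertFormat("SDF", "CAN", source = src),
                  error = function(e) NA_character_)
  if (is.na(out) || !nzchar(trimws(out))) return(NA_character_)
  strsplit(out, "[\t\n ]")[[1]][1]
}

parse_datablock <- function(db) {
  if (!length(db)) return(tibble::tibble(.rows = 1))
  vals <- as.list(db)
  tags <- names(vals)
  out <- list()
  for (t in tags) {
    col <- names(.tag_map)[match(t, .tag_map)]
    if (is.na(col)) col <- t
    v <- vals[[t]]
    out[[col]] <- parse_tag_value(col, v)
  }
  tibble::as_tibble(out)
}

parse_tag_value <- function(col, v) {
  if (col %in% c("pf_pass", "is_virtual_hit")) {
    return(tolower(v) %in% c("true", "1", "yes"))
  }
  if (col %in% c("sascore", "qed", "delta_g", "cluster_size")) {
    num <- suppressWarnings(as.numeric(v))
    if (col == "cluster_size") return(as.integer(num))
    return(num)
  }
  # unknown tags: numeric when they look numeric, else character
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num) && grepl("^[-+0-9.eE]+$", trimws(v))) num else v
}

finish_read <- function(records, rejects) {
  mols <- if (length(records)) dplyr::bind_rows(records) else
    tibble::tibble(record_id = character(), smiles = character(),
                   mol = list())
  if (anyDuplicated(mols$record_id)) {
    mols$record_id <- make.unique(mols$record_id, sep = "_dup")
  }
  mols <- as_mol_tbl(mols)
  rej <- if (length(rejects)) dplyr::bind_rows(rejects) else
    tibble::tibble(index = integer(), id = character(), reason = character())
  mol_rejects(mols) <- rej
  mols
}

#' Write a molecule table to an SDF (V2000) file
#'
#' Declared annotation columns are emitted as SDF data items under their
#' bit-exact tag names (`PF_PASS`, `SAS`, `QED`, `GBVI_WSA_dG`, `HIT`,
#' `CLUSTER_ID`, `CLUSTER_SIZE`, `SCAFFOLD_SMILES`); any other requested
#' column is written under its own name. Records without a structure column
#' are laid out from their SMILES with zeroed-template 2-D coordinates.
#'
#' @param mols A molecule table.
#' @param path Output path.
#' @param tags Character vector of annotation column names to write; default
#'   every mapped column present in `mols`. Missing values are written as
#'   empty strings (`policy = "empty"`) or the tag is skipped for that record
#'   (`policy = "skip"`).
#' @param policy Missing-tag policy, `"empty"` or `"skip"`.
#' @return Invisibly, `path`.
#' @export
write_molecules <- function(mols, path,
                            tags = intersect(names(.tag_map), names(mols)),
                            policy = c("empty", "skip")) {
  policy <- match.arg(policy)
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(paste0("cannot open path for writing: ", path))
  })
  on.exit(close(con))
  for (i in seq_len(nrow(mols))) {
    sdf <- if ("mol" %in% names(mols)) mols$mol[[i]] else NULL
    if (is.null(sdf)) sdf <- smiles_to_sdf_one(mols$smiles[i])
    if (is.null(sdf)) next
    lines <- sdf_block_lines(sdf, mols$record_id[i])
    lines <- lines[!grepl("^M  END", lines)]
    lines <- c(lines, "M  END")
    for (tg in tags) {
      val <- mols[[tg]][i]
      tag_name <- .tag_map[tg]
      if (is.na(tag_name)) tag_name <- tg
      if (is.na(val) || (is.character(val) && !nzchar(val) && policy == "skip")) {
        if (policy == "skip") next
        val <- ""
      }
      val <- format_tag_value(val)
      lines <- c(lines, paste0(">  <", tag_name, ">"), val, "")
    }
    writeLines(c(lines, "$$$$"), con)
  }
  invisible(path)
}

format_tag_value <- function(val) {
  if (is.logical(val)) return(if (isTRUE(val)) "true" else "false")
  if (is.numeric(val)) return(format(val, scientific = FALSE, trim = TRUE,
                                     digits = 15))
  as.character(val)
}

# Reconstruct a V2000 molblock from a ChemmineR SDF object with a fixed
# program line so output is byte-stable across runs.
sdf_block_lines <- function(sdf, record_id) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab); m <- if (is.null(bb)) 0L else nrow(bb)
  element <- sub("_.*$", "", rownames(ab))
  header <- c(record_id, "  hittriage", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m)
  atoms <- vapply(seq_len(n), function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
            ab[i, 1], ab[i, 2], ab[i, 3], element[i], as.integer(ab[i, 5]))
  }, character(1))
  bonds <- if (m) vapply(seq_len(m), function(k) {
    sprintf("%3d%3d%3d  0  0  0  0",
            as.integer(bb[k, 1]), as.integer(bb[k, 2]), as.integer(bb[k, 3]))
  }, character(1)) else character(0)
  chg <- which(.mdl_charge[as.character(as.integer(ab[, 5]))] != 0)
  mchg <- character(0)
  if (length(chg)) {
    q <- .mdl_charge[as.character(as.integer(ab[chg, 5]))]
    mchg <- paste0("M  CHG", sprintf("%3d", length(chg)),
                   paste0(sprintf("%4d%4d", chg, q), collapse = ""))
  }
  c(header, counts, atoms, bonds, mchg, "M  END")
}

#' Validate molecule structures
#'
#' Structure-level sanity checks applied before any filtering: element
#' symbols must be known (`atom_type`), no atom may exceed its maximum
#' allowed valence given its formal charge (`valence`), formal charges must
#' be within a plausible range (`charge`), and the record must have parsed at
#' all (`parse`). Validation is total: every record yields a report row and
#' no input throws.
#'
#' @param mols A molecule table.
#' @return A tibble `record_id`, `is_valid`, `failures` (list-column of
#'   character vectors drawn from `atom_type`, `valence`, `charge`, `parse`).
#' @export
validate_molecules <- function(mols) {
  out <- purrr::map(seq_len(nrow(mols)), function(i) {
    sdf <- if ("mol" %in% names(mols)) mols$mol[[i]] else NULL
    fails <- character(0)
    if (is.null(sdf)) {
      fails <- "parse"
    } else {
      g <- tryCatch(mol_graph(sdf), error = function(e) NULL)
      if (is.null(g)) {
        fails <- "parse"
      } else {
        if (!all(g$element %in% names(.element_z))) fails <- c(fails, "atom_type")
        if (any(abs(g$charge) > 3)) fails <- c(fails, "charge")
        if (valence_violation(g)) fails <- c(fails, "valence")
      }
    }
    tibble::tibble(record_id = mols$record_id[i],
                   is_valid = length(fails) == 0,
                   failures = list(fails))
  })
  dplyr::bind_rows(out)
}

# Max allowed valence (sum of bond orders to explicit neighbours), charge
# adjusted; hypervalent S/P allowed up to their common oxidation states.
.max_valence <- c(H = 1, B = 4, C = 4, N = 4, O = 3, F = 1, Si = 4, P = 5,
                  S = 6, Cl = 1, Br = 1, I = 3)

valence_violation <- function(g) {
  if (!nrow(g$bonds)) return(FALSE)
  ord <- g$bonds[, 3]
  ord[ord == 4L] <- 1L
  for (i in seq_len(g$n)) {
    el <- g$element[i]
    if (!el %in% names(.max_valence)) next
    k <- g$bonds[, 1] == i | g$bonds[, 2] == i
    tot <- sum(ord[k])
    cap <- .max_valence[el] + max(0L, g$charge[i])
    if (el == "C") cap <- 4L  # carbon never exceeds 4 regardless of charge
    if (tot > cap) return(TRUE)
  }
  FALSE
}
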