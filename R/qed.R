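# Quantitative estimate of drug-likeness (QED): weighted geometric mean of
# eight property desirabilities, each an asymmetric double sigmoid (ADS)
# with the published parameterisation. The underlying descriptors (HBA, HBD,
# logP, TPSA) come from OpenBabel, aromatic-ring and alert counts from SMARTS
# matching, and rotatable bonds from the package's graph definition, so
# absolute QED values differ slightly from other toolkits while the
# functional form is exact.

# ADS parameters (a, b, c, d, e, f, dmax) per property, published set.
.qed_ads <- matrix(c(
  2.817065973, 392.5754953, 290.7489764, 2.419764353, 49.22325677, 65.37051707, 104.9805561,
  3.172690585, 137.8624751, 2.534937431, 4.581497897, 0.822739154, 0.576295591, 131.3186604,
  2.948620388, 160.4605972, 3.615294657, 4.435986202, 0.290141953, 1.300669958, 148.7763046,
  1.618662227, 1010.051101, 0.985094388, 0.000000001, 0.713820843, 0.920922555, 258.1632616,
  1.876861559, 125.2232657, 62.90773554, 87.83366614, 12.01999824, 28.51324732, 104.5686167,
  0.010000091, 272.4121427, 2.558379970, 1.565547684, 1.271567166, 2.758063707, 105.4420403,
  3.217788970, 957.7374108, 2.274627939, 0.000000001, 1.317690384, 0.375760881, 312.3372610,
  0.010000000, 1199.094025, -0.09002883, 0.000000001, 0.185904477, 0.875193782, 417.7253140
), nrow = 8, byrow = TRUE,
  dimnames = list(c("mw", "alogp", "hba", "hbd", "psa", "rotb", "arom", "alerts"),
                  c("a", "b", "c", "d", "e", "f", "dmax")))

ads <- function(x, p) {
  v <- p["a"] + p["b"] /
    (1 + exp(-(x - p["c"] + p["d"] / 2) / p["e"])) *
    (1 - 1 / (1 + exp(-(x - p["c"] - p["d"] / 2) / p["f"])))
  pmax(v / p["dmax"], 1e-9)
}

#' QED weight sets
#'
#' The published weighting schemes: `"mean"` (default; weights that maximise
#' mean information content), `"max"`, and `"unit"` (all ones, i.e. the plain
#' geometric mean).
#'
#' @param scheme One of `"mean"`, `"max"`, `"unit"`, or a named numeric
#'   vector over `mw, alogp, hba, hbd, psa, rotb, arom, alerts`.
#' @return Named numeric vector of eight non-negative weights.
#' @export
qed_weights <- function(scheme = c("mean", "max", "unit")) {
  if (is.numeric(scheme)) {
    stopifnot(length(scheme) == 8, all(scheme >= 0), any(scheme > 0))
    return(setNames(as.numeric(scheme), rownames(.qed_ads)))
  }
  scheme <- match.arg(scheme)
  w <- switch(scheme,
    mean = c(0.66, 0.46, 0.05, 0.61, 0.06, 0.65, 0.48, 0.95),
    max  = c(0.50, 0.25, 0.00, 0.50, 0.00, 0.50, 0.25, 1.00),
    unit = rep(1, 8)
  )
  setNames(w, rownames(.qed_ads))
}

#' QED from raw desirabilities
#'
#' The exact weighted-geometric-mean form:
#' `QED = exp( sum(w_i * ln d_i) / sum(w_i) )`. Exposed separately so the
#' algebra is testable independently of descriptor computation. A zero
#' desirability yields QED 0 with a warning (limit convention for `ln 0`).
#'
#' @param d Numeric vector of eight desirabilities in `[0, 1]`.
#' @param w Weights from [qed_weights()].
#' @return QED value in `[0, 1]`.
#' @export
qed_from_desirabilities <- function(d, w = qed_weights("mean")) {
  stopifnot(length(d) == length(w), sum(w) > 0)
  if (any(d < 0 | d > 1)) abort("desirabilities must lie in [0, 1]")
  if (any(d == 0)) {
    warn("zero desirability: QED is 0 by the limit convention")
    return(0)
  }
  exp(sum(w * log(d)) / sum(w))
}

#' Compute QED for every molecule
#'
#' Adds `qed` (and the eight `qed_d_*` desirability columns) to the molecule
#' table. Descriptors used: molecular weight, atomic-contribution logP,
#' hydrogen-bond acceptors/donors (OpenBabel), topological PSA, rotatable
#' bonds (graph definition), aromatic ring count (SMARTS), and structural
#' alert count from the bundled alert SMARTS list.
#'
#' @param mols A molecule table.
#' @param weights Weight vector from [qed_weights()].
#' @param keep_desirabilities Keep the per-property desirability columns?
#' @return `mols` with `qed` added.
#' @export
compute_qed <- function(mols, weights = qed_weights("mean"),
                        keep_desirabilities = FALSE) {
  n <- nrow(mols)
  mols$qed <- rep(NA_real_, n)
  if (!n) return(mols)
  sdfset <- mols_as_sdfset(mols)
  ok <- which(sdfset$keep)
  if (!length(ok)) return(mols)
  props <- tryCatch(ob_props(sdfset$list), error = function(e) NULL)
  if (is.null(props) || nrow(props) != length(ok)) return(mols)
  rotb <- vapply(ok, function(i) {
    count_rotatable_bonds(mol_graph(sdfset$list[[i]]))
  }, integer(1))
  arom <- aromatic_ring_count(sdfset$list)
  alerts <- alert_count(sdfset$list)
  d <- cbind(
    mw     = ads(props$MW,   .qed_ads["mw", ]),
    alogp  = ads(props$logP, .qed_ads["alogp", ]),
    hba    = ads(props$HBA1, .qed_ads["hba", ]),
    hbd    = ads(props$HBD,  .qed_ads["hbd", ]),
    psa    = ads(props$TPSA, .qed_ads["psa", ]),
    rotb   = ads(rotb,       .qed_ads["rotb", ]),
    arom   = ads(arom,       .qed_ads["arom", ]),
    alerts = ads(alerts,     .qed_ads["alerts", ])
  )
  d <- pmin(d, 1)
  qed <- exp(as.vector(log(d) %*% weights) / sum(weights))
  mols$qed[ok] <- qed
  if (keep_desirabilities) {
    for (p in colnames(d)) {
      col <- paste0("qed_d_", p)
      mols[[col]] <- rep(NA_real_, n)
      mols[[col]][ok] <- d[, p]
    }
  }
  mols
}

# aromatic ring count via unique SMARTS ring matches (5-7 membered)
aromatic_ring_count <- function(sdf_list) {
  pats <- c("a1aaaa1", "a1aaaaa1", "a1aaaaaa1")
  n <- sum(!vapply(sdf_list, is.null, logical(1)))
  counts <- rep(0, n)
  for (p in pats) {
    m <- ob_smarts_count(sdf_list, p, unique_matches = TRUE)
    if (length(m) == n) counts <- counts + m
  }
  counts
}

# structural alerts: bundled SMARTS list (undesirable functionality)
.alert_env <- new.env(parent = emptyenv())

alert_smarts <- function() {
  if (is.null(.alert_env$pats)) {
    f <- system.file("extdata", "alert_smarts.txt", package = "hittriage")
    lines <- readLines(f, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    .alert_env$pats <- lines[nzchar(lines)]
  }
  .alert_env$pats
}

alert_count <- function(sdf_list) {
  n <- sum(!vapply(sdf_list, is.null, logical(1)))
  counts <- rep(0, n)
  for (p in alert_smarts()) {
    m <- ob_smarts_count(sdf_list, p, unique_matches = TRUE)
    if (length(m) == n) counts <- counts + as.numeric(m > 0)
  }
  counts
}
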