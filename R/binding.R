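# Surrogate binding scorer with the GBVI/WSA functional form:
#
#   dG = c + alpha * [ 2/3 (E_Coul + E_sol) + E_vdW + beta * SA_weighted ]
#
# Point-charge Coulomb electrostatics at interior dielectric 1, generalized
# Born solvation with pairwise (HCT-style) descreening, Lennard-Jones 6-12
# van der Waals with geometric mixing, and a solvent-accessible surface term
# weighted by exposure. The trained constants of the commercial scorer are
# not public; defaults are the surrogate values c = 0, alpha = 1, beta = 0.1.
# If a molecule table already carries an external score (tag GBVI_WSA_dG /
# column delta_g), score_binding() leaves it untouched.

.kcoul <- 332.0636   # kcal mol^-1 A e^-2
.eps_water <- 80

#' Binding-score parameters
#'
#' @param c Rotational/translational entropy constant (kcal/mol).
#' @param alpha,beta Trained linear constants (surrogate defaults 1, 0.1).
#' @param dielectric Interior dielectric for the Coulomb term (default 1).
#' @param clash_cutoff Distance (A) below which a pose is flagged as
#'   clashing; the score is still computed.
#' @param probe Solvent probe radius (A) for the surface term.
#' @return Named list of parameters.
#' @export
binding_params <- function(c = 0, alpha = 1, beta = 0.1, dielectric = 1,
                           clash_cutoff = 1.0, probe = 1.4) {
  list(c = c, alpha = alpha, beta = beta, dielectric = dielectric,
       clash_cutoff = clash_cutoff, probe = probe)
}

#' Read a receptor from PDB with an optional charge/radius sidecar
#'
#' @param pdb_path Path to a PDB file.
#' @param charges_path Optional CSV `atom_serial, charge, radius` overriding
#'   the defaults (charge 0, element vdW radius).
#' @return A tibble `element, x, y, z, charge, radius` with class
#'   `receptor`.
#' @export
read_receptor <- function(pdb_path, charges_path = NULL) {
  pdb <- bio3d::read.pdb(pdb_path)
  at <- pdb$atom
  element <- trimws(at$elesy)
  element[!nzchar(element)] <- substr(trimws(at$elety[!nzchar(element)]), 1, 1)
  rec <- tibble::tibble(
    serial = at$eleno, element = element,
    x = at$x, y = at$y, z = at$z,
    charge = 0, radius = unname(.vdw_radius[element])
  )
  rec$radius[is.na(rec$radius)] <- 1.7
  if (!is.null(charges_path)) {
    side <- read.csv(charges_path, stringsAsFactors = FALSE)
    idx <- match(rec$serial, side$atom_serial)
    hit <- !is.na(idx)
    if ("charge" %in% names(side)) rec$charge[hit] <- side$charge[idx[hit]]
    if ("radius" %in% names(side)) rec$radius[hit] <- side$radius[idx[hit]]
  }
  class(rec) <- c("receptor", class(rec))
  rec
}

#' Translate a conformer
#'
#' Rigid translation of an SDF conformer; with `center` given, the heavy-atom
#' centroid is moved onto it (e.g. a pocket centroid) before the offset is
#' applied.
#'
#' @param sdf A `ChemmineR::SDF` object with coordinates.
#' @param offset Length-3 translation vector (Angstrom).
#' @param center Optional length-3 target for the heavy-atom centroid.
#' @return The translated `SDF` object.
#' @export
translate_conformer <- function(sdf, offset = c(0, 0, 0), center = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  if (!is.null(center)) {
    heavy <- !grepl("^H_", rownames(ab))
    ctr <- colMeans(ab[heavy, 1:3, drop = FALSE])
    ab[, 1:3] <- sweep(ab[, 1:3, drop = FALSE], 2, ctr - center)
  }
  ab[, 1] <- ab[, 1] + offset[1]
  ab[, 2] <- ab[, 2] + offset[2]
  ab[, 3] <- ab[, 3] + offset[3]
  methods::slot(sdf, "atomblock") <- ab
  sdf
}

#' Score ligand poses against a receptor
#'
#' Computes the four energy terms and the combined score for every molecule
#' with a 3-D conformer. Records already carrying a `delta_g` value (an
#' externally supplied score) are skipped and keep their value: external
#' scores win. Poses with any ligand-receptor contact below `clash_cutoff`
#' are flagged in `clash` but still scored.
#'
#' @param mols Molecule table; conformers are taken from the `mol` column
#'   (in the receptor frame).
#' @param receptor From [read_receptor()] or [generate_toy_receptor()].
#' @param params From [binding_params()].
#' @return `mols` with `e_coul`, `e_sol`, `e_vdw`, `sa_weighted`, `delta_g`
#'   and `clash` columns.
#' @export
score_binding <- function(mols, receptor, params = binding_params()) {
  n <- nrow(mols)
  for (col in c("e_coul", "e_sol", "e_vdw", "sa_weighted")) {
    if (!col %in% names(mols)) mols[[col]] <- rep(NA_real_, n)
  }
  if (!"delta_g" %in% names(mols)) mols$delta_g <- rep(NA_real_, n)
  if (!"clash" %in% names(mols)) mols$clash <- rep(FALSE, n)
  external <- !is.na(mols$delta_g)
  for (i in seq_len(n)) {
    if (external[i]) next
    sdf <- mols$mol[[i]]
    if (is.null(sdf)) next
    terms <- binding_terms(sdf, receptor, params)
    mols$e_coul[i] <- terms$e_coul
    mols$e_sol[i] <- terms$e_sol
    mols$e_vdw[i] <- terms$e_vdw
    mols$sa_weighted[i] <- terms$sa_weighted
    mols$delta_g[i] <- terms$delta_g
    mols$clash[i] <- terms$clash
  }
  mols
}

# UFF-style Lennard-Jones parameters: x = minimum-energy distance (A),
# d = well depth (kcal/mol)
.lj_x <- c(H = 2.886, B = 4.083, C = 3.851, N = 3.660, O = 3.500, F = 3.364,
           Si = 4.295, P = 4.147, S = 4.035, Cl = 3.947, Br = 4.189, I = 4.50)
.lj_d <- c(H = 0.044, B = 0.180, C = 0.105, N = 0.069, O = 0.060, F = 0.050,
           Si = 0.402, P = 0.305, S = 0.274, Cl = 0.227, Br = 0.251, I = 0.339)

binding_terms <- function(sdf, receptor, params) {
  g <- mol_graph(sdf)
  lig <- list(
    element = g$element, xyz = g$xyz,
    charge = ligand_partial_charges(sdf, g),
    radius = unname(.vdw_radius[g$element])
  )
  lig$radius[is.na(lig$radius)] <- 1.7
  rec <- list(element = receptor$element,
              xyz = cbind(receptor$x, receptor$y, receptor$z),
              charge = receptor$charge, radius = receptor$radius)

  d <- cross_distances(lig$xyz, rec$xyz)
  clash <- any(d < params$clash_cutoff)
  d_safe <- pmax(d, 0.5)

  e_coul <- .kcoul / params$dielectric *
    sum(outer(lig$charge, rec$charge) / d_safe)

  xl <- .lj_x[lig$element]; xl[is.na(xl)] <- 3.85
  xr <- .lj_x[rec$element]; xr[is.na(xr)] <- 3.85
  dl <- .lj_d[lig$element]; dl[is.na(dl)] <- 0.105
  dr <- .lj_d[rec$element]; dr[is.na(dr)] <- 0.105
  xij <- sqrt(outer(xl, xr))
  dij <- sqrt(outer(dl, dr))
  rr <- (xij / d_safe)
  # pairwise repulsion softened at 10 kcal/mol so clashing poses stay on a
  # finite, comparable scale (they are additionally flagged via clash)
  e_vdw <- sum(pmin(dij * (rr^12 - 2 * rr^6), 10))

  e_sol <- gb_solvation_change(lig, rec, d_safe)

  # change in exposure-weighted ligand surface on binding: burial makes the
  # term negative (favourable with beta > 0); a non-interacting pose gives 0
  sa_weighted <- weighted_surface_term(lig, rec, params$probe) -
    weighted_surface_term(lig, NULL, params$probe)

  delta_g <- params$c + params$alpha *
    ((2 / 3) * (e_coul + e_sol) + e_vdw + params$beta * sa_weighted)
  list(e_coul = e_coul, e_sol = e_sol, e_vdw = e_vdw,
       sa_weighted = sa_weighted, delta_g = delta_g, clash = clash)
}

# Gasteiger partial charges from OpenBabel via MOL2 conversion; falls back to
# formal charges if conversion fails.
ligand_partial_charges <- function(sdf, g) {
  txt <- paste0(paste(sdf_block_lines(sdf, "lig"), collapse = "\n"),
                "\n$$$$\n")
  mol2 <- tryCatch(ChemmineOB::convertFormat("SDF", "MOL2", source = txt),
                   error = function(e) NA_character_)
  if (!is.na(mol2)) {
    lines <- strsplit(mol2, "\n")[[1]]
    a0 <- grep("@<TRIPOS>ATOM", lines, fixed = TRUE)
    a1 <- grep("@<TRIPOS>BOND", lines, fixed = TRUE)
    if (length(a0) && length(a1) && a1 > a0 + 1) {
      rows <- lines[(a0 + 1):(a1 - 1)]
      q <- suppressWarnings(as.numeric(vapply(strsplit(trimws(rows), "[ \t]+"),
                                              function(p) p[length(p)],
                                              character(1))))
      if (length(q) == g$n && !anyNA(q)) return(q)
    }
  }
  as.numeric(g$charge)
}

cross_distances <- function(a, b) {
  da <- outer(a[, 1], b[, 1], "-")
  db <- outer(a[, 2], b[, 2], "-")
  dc <- outer(a[, 3], b[, 3], "-")
  sqrt(da^2 + db^2 + dc^2)
}

# Generalized Born polar solvation of a set of atoms (Still's formula) with
# HCT pairwise descreening for the effective Born radii.
gb_energy <- function(xyz, charge, rho) {
  n <- length(charge)
  if (n == 0) return(0)
  d <- cross_distances(xyz, xyz)
  born <- born_radii(d, rho)
  fgb <- sqrt(d^2 + outer(born, born) * exp(-d^2 / (4 * outer(born, born))))
  diag(fgb) <- born
  -0.5 * .kcoul * (1 - 1 / .eps_water) * sum(outer(charge, charge) / fgb)
}

born_radii <- function(d, rho, scale = 0.8) {
  n <- length(rho)
  inv <- 1 / rho
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      if (i == j) next
      r <- d[i, j]
      srho <- scale * rho[j]
      if (rho[i] >= r + srho) next
      L <- max(abs(r - srho), rho[i])
      U <- r + srho
      s <- s + 0.5 * (1 / L - 1 / U + (r - srho^2 / r) *
                        (1 / U^2 - 1 / L^2) / 4 + log(L / U) / (2 * r))
    }
    inv[i] <- max(1 / rho[i] - s, 1e-3)
  }
  1 / inv
}

gb_solvation_change <- function(lig, rec, d_cross) {
  xyz_all <- rbind(lig$xyz, rec$xyz)
  q_all <- c(lig$charge, rec$charge)
  rho_all <- c(lig$radius, rec$radius)
  gb_energy(xyz_all, q_all, rho_all) -
    gb_energy(lig$xyz, lig$charge, lig$radius) -
    gb_energy(rec$xyz, rec$charge, rec$radius)
}

# Deterministic sphere point set (golden spiral) for surface exposure.
sphere_points <- function(k = 92) {
  i <- seq_len(k) - 0.5
  phi <- acos(1 - 2 * i / k)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Exposure-weighted surface area of the bound ligand: sum over ligand atoms
# of (exposed SASA in complex) x (exposure fraction). Exposed surface is
# penalised by beta > 0 in the combined score.
weighted_surface_term <- function(lig, rec, probe) {
  pts <- sphere_points()
  nl <- nrow(lig$xyz)
  all_xyz <- rbind(lig$xyz, if (!is.null(rec)) rec$xyz)
  all_rad <- c(lig$radius, if (!is.null(rec)) rec$radius) + probe
  total <- 0
  for (i in seq_len(nl)) {
    ri <- lig$radius[i] + probe
    surf <- sweep(pts * ri, 2, lig$xyz[i, ], "+")
    exposed <- rep(TRUE, nrow(surf))
    for (j in seq_len(nrow(all_xyz))) {
      if (j == i) next
      dj <- sqrt(colSums((t(surf) - all_xyz[j, ])^2))
      exposed <- exposed & dj > all_rad[j]
      if (!any(exposed)) break
    }
    frac <- mean(exposed)
    total <- total + 4 * pi * ri^2 * frac * frac
  }
  total
}
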