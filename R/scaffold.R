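# Bemis-Murcko assemblies: ring systems plus chains linking two or more
# rings, with all other substituent chains removed. Computed by iterative
# leaf pruning of the heavy-atom graph (ring atoms and inter-ring linkers
# are exactly the atoms that survive), then restoring atoms attached to the
# framework by a double or triple bond (the "assemblies" convention keeps
# exocyclic carbonyls and the like).

#' Bemis-Murcko assembly scaffold
#'
#' Adds a `scaffold_smiles` column (SDF tag `SCAFFOLD_SMILES`): the canonical
#' SMILES of the molecule's ring-and-linker framework, or `""` for acyclic
#' molecules. Scaffold extraction is idempotent: the scaffold of a scaffold
#' is itself.
#'
#' @param mols A molecule table (or a single `ChemmineR::SDF` object, in
#'   which case the scaffold string is returned directly).
#' @return `mols` with `scaffold_smiles` added, or a character scalar.
#' @export
#' @examples
#' mols <- mol_tbl(c("a", "b"), c("Cc1ccccc1", "CCCCCC"),
#'                 list(smiles_to_sdf_one("Cc1ccccc1"),
#'                      smiles_to_sdf_one("CCCCCC")))
#' murcko_assembly(mols)$scaffold_smiles  # benzene and ""
murcko_assembly <- function(mols) {
  if (inherits(mols, "SDF")) return(murcko_one(mols))
  sdfset <- mols_as_sdfset(mols)
  mols$scaffold_smiles <- vapply(seq_len(nrow(mols)), function(i) {
    sdf <- sdfset$list[[i]]
    if (is.null(sdf)) return(NA_character_)
    murcko_one(sdf)
  }, character(1))
  mols
}

murcko_one <- function(sdf) {
  g <- mol_graph(sdf)
  if (!any(g$ring_atom)) return("")
  keep <- g$heavy
  # iterative leaf pruning on the heavy-atom graph
  repeat {
    deg <- vapply(seq_len(g$n), function(i) {
      if (!keep[i]) return(0L)
      sum(keep[g$adj[[i]]])
    }, integer(1))
    leaves <- which(keep & deg <= 1L & !g$ring_atom)
    if (!length(leaves)) break
    keep[leaves] <- FALSE
  }
  # restore atoms multiply bonded to the framework (exocyclic =O, =N, etc.)
  if (nrow(g$bonds)) {
    repeat {
      added <- FALSE
      for (k in seq_len(nrow(g$bonds))) {
        if (g$bonds[k, 3] < 2L) next
        i <- g$bonds[k, 1]; j <- g$bonds[k, 2]
        if (keep[i] && !keep[j] && g$heavy[j]) { keep[j] <- TRUE; added <- TRUE }
        if (keep[j] && !keep[i] && g$heavy[i]) { keep[i] <- TRUE; added <- TRUE }
      }
      if (!added) break
    }
  }
  if (!any(keep)) return("")
  sub_sdf <- subgraph_sdf(sdf, which(keep))
  smi <- sdf_to_canonical_smiles(c(sdf_block_lines(sub_sdf, "scaffold"), "$$$$"))
  if (is.na(smi)) "" else smi
}

# Extract the induced subgraph of an SDF on a set of atom indices.
subgraph_sdf <- function(sdf, atoms) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  map <- setNames(seq_along(atoms), atoms)
  new_ab <- ab[atoms, , drop = FALSE]
  keep_b <- which(bb[, 1] %in% atoms & bb[, 2] %in% atoms)
  new_bb <- bb[keep_b, , drop = FALSE]
  if (nrow(new_bb)) {
    new_bb[, 1] <- map[as.character(new_bb[, 1])]
    new_bb[, 2] <- map[as.character(new_bb[, 2])]
  }
  methods::new("SDF",
               header = c(Molecule_Name = "scaffold", Source = "  hittriage",
                          Comment = "", Counts_Line = ""),
               atomblock = new_ab, bondblock = new_bb, datablock = character(0))
}

#' Fingerprint a vector of scaffold SMILES
#'
#' Circular fingerprint (radius 3, 2048 bits) of each scaffold. The empty
#' scaffold (acyclic molecules) maps to the reserved all-zero vector, which
#' the clustering routes to the `NO_SCAFFOLD` pseudo-cluster.
#'
#' @param scaffold_smiles Character vector.
#' @param nbits,radius Fingerprint parameters.
#' @return A 0/1 integer matrix, one row per scaffold.
#' @export
scaffold_fingerprint <- function(scaffold_smiles, nbits = 2048, radius = 3) {
  out <- matrix(0L, nrow = length(scaffold_smiles), ncol = nbits)
  uniq <- unique(scaffold_smiles[!is.na(scaffold_smiles) &
                                   nzchar(scaffold_smiles)])
  for (s in uniq) {
    sdf <- smiles_to_sdf_one(s)
    if (is.null(sdf)) next
    fp <- morgan_fingerprint(sdf, radius = radius, nbits = nbits)
    idx <- which(!is.na(scaffold_smiles) & scaffold_smiles == s)
    out[idx, ] <- matrix(fp, nrow = length(idx), ncol = nbits, byrow = TRUE)
  }
  out
}
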