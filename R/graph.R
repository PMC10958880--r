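# Light molecular-graph layer over ChemmineR SDF objects. Everything that
# needs connectivity (rotatable bonds, ring membership, Murcko pruning,
# circular fingerprints, pharmacophore typing) goes through mol_graph().

.element_z <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, Br = 35, I = 53
)

.atomic_mass <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.086, P = 30.974, S = 32.06, Cl = 35.453, Br = 79.904, I = 126.904
)

# default valences used for implicit-H bookkeeping; charge-adjusted below
.default_valence <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

# van der Waals radii (Bondi), Angstrom
.vdw_radius <- c(
  H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47, Si = 2.10,
  P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98
)

# MDL atom-line charge codes -> formal charge
.mdl_charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

#' Molecular graph view of an SDF record
#'
#' Extracts elements, coordinates, formal charges, the bond list, ring
#' membership (bonds not in any ring are graph bridges) and implicit hydrogen
#' counts from a `ChemmineR::SDF` object.
#'
#' @param sdf A `ChemmineR::SDF` object.
#' @return A list with fields `n`, `element`, `xyz`, `charge`, `bonds`
#'   (matrix from/to/order), `adj` (adjacency list), `ring_bond`, `ring_atom`,
#'   `degree`, `n_h` (implicit + explicit attached hydrogens per heavy atom).
#' @keywords internal
mol_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  element <- sub("_.*$", "", rownames(ab))
  xyz <- unname(ab[, 1:3, drop = FALSE])
  ccode <- as.character(as.integer(ab[, 5]))
  charge <- unname(.mdl_charge[ccode])
  charge[is.na(charge)] <- 0L

  if (is.null(bb) || nrow(bb) == 0) {
    bonds <- matrix(integer(0), ncol = 3,
                    dimnames = list(NULL, c("from", "to", "order")))
  } else {
    bonds <- cbind(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
  }

  adj <- vector("list", n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  degree <- lengths(adj)

  ring_bond <- if (nrow(bonds)) !bridge_bonds(n, bonds) else logical(0)
  ring_atom <- rep(FALSE, n)
  if (any(ring_bond)) {
    ring_atom[unique(as.vector(bonds[ring_bond, 1:2]))] <- TRUE
  }

  # hydrogens: explicit H neighbours plus implicit count from default valence
  heavy <- element != "H"
  bond_order_sum <- rep(0L, n)
  if (nrow(bonds)) {
    ord <- bonds[, 3]
    ord[ord == 4L] <- 1L  # aromatic type treated as single for valence floor
    bond_order_sum <- as.integer(
      tabulate(bonds[, 1], n) * 0 +
        vapply(seq_len(n), function(i) {
          k <- bonds[, 1] == i | bonds[, 2] == i
          sum(ord[k])
        }, integer(1))
    )
  }
  val <- unname(.default_valence[element])
  val[is.na(val)] <- 0L
  # charge-adjusted valence: N+ -> 4, O- -> 1, C+/- -> 3, etc.
  val <- val + ifelse(element %in% c("N", "P"), charge,
               ifelse(element %in% c("O", "S"), charge,
               ifelse(element == "C", -abs(charge), 0L)))
  n_h_implicit <- pmax(0L, val - bond_order_sum)
  n_h_explicit <- vapply(seq_len(n), function(i) {
    sum(element[adj[[i]]] == "H")
  }, integer(1))
  n_h <- n_h_implicit + n_h_explicit
  n_h[!heavy] <- 0L

  list(n = n, element = element, xyz = xyz, charge = charge, bonds = bonds,
       adj = adj, degree = degree, ring_bond = ring_bond,
       ring_atom = ring_atom, n_h = n_h, heavy = heavy)
}

# Bridge detection (Tarjan). A bond is in a ring iff it is not a bridge.
bridge_bonds <- function(n, bonds) {
  m <- nrow(bonds)
  if (m == 0) return(logical(0))
  # adjacency with edge indices
  adj <- vector("list", n)
  for (k in seq_len(m)) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- rbind(adj[[i]], c(j, k))
    adj[[j]] <- rbind(adj[[j]], c(i, k))
  }
  disc <- rep(0L, n); low <- rep(0L, n)
  is_bridge <- rep(FALSE, m)
  timer <- 0L
  # iterative DFS to avoid deep recursion on long chains
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    stack <- list(list(v = root, parent_edge = 0L, idx = 1L))
    timer <- timer + 1L
    disc[root] <- low[root] <- timer
    while (length(stack)) {
      top <- stack[[length(stack)]]
      v <- top$v
      nb <- adj[[v]]
      if (is.null(nb) || top$idx > nrow(nb)) {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          p <- stack[[length(stack)]]
          u <- p$v
          low[u] <- min(low[u], low[v])
          if (low[v] > disc[u]) is_bridge[top$parent_edge] <- TRUE
        }
        next
      }
      stack[[length(stack)]]$idx <- top$idx + 1L
      w <- nb[top$idx, 1]; ek <- nb[top$idx, 2]
      if (ek == top$parent_edge) next
      if (disc[w] == 0L) {
        timer <- timer + 1L
        disc[w] <- low[w] <- timer
        stack[[length(stack) + 1L]] <- list(v = w, parent_edge = ek, idx = 1L)
      } else {
        low[v] <- min(low[v], disc[w])
      }
    }
  }
  is_bridge
}

# Connected components of an induced subgraph (by atom index subset).
graph_components <- function(keep, adj) {
  idx <- which(keep)
  comp <- rep(NA_integer_, length(keep))
  cur <- 0L
  for (s in idx) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (keep[w] && is.na(comp[w])) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}
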