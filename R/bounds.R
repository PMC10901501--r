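# Distance-geometry bounds matrix: per-heavy-atom-pair lower/upper distance
# limits derived from molecular topology alone (ideal bond lengths from
# covalent radii with bond-order corrections, ideal angles from
# hybridisation and ring geometry, van der Waals contact floors for
# non-bonded pairs), followed by triangle-inequality smoothing. The bond
# length, bond angle and internal clash checks all read from this one
# matrix.

BOND_ORDER_FACTOR <- c(`1` = 1.00, `2` = 0.87, `3` = 0.78, `4` = 0.915)
BOND_TOL <- 0.06        # Angstrom half-width around the ideal bond length
ANGLE_CHORD_TOL <- 0.12 # half-width around the ideal 1-3 chord
RING_CHORD_TOL <- 0.15  # half-width for cross-ring chords in aromatic rings
NONBONDED_14_SCALE <- 0.8
UPPER_INIT <- 999

ideal_bond_length <- function(el_i, el_j, order, radii = radii_table()) {
  rc <- element_radius(c(el_i, el_j), "covalent", radii)
  fac <- BOND_ORDER_FACTOR[as.character(order)]
  if (is.na(fac)) fac <- 1.0
  unname((rc[1] + rc[2]) * fac)
}

chord <- function(b1, b2, theta_deg) {
  sqrt(b1^2 + b2^2 - 2 * b1 * b2 * cos(theta_deg * pi / 180))
}

ideal_angle <- function(el, hyb) {
  if (hyb == "sp") return(180)
  if (hyb == "sp2") return(120)
  if (el == "O") return(104.5)
  if (el == "S") return(100)
  109.47
}

#' Distance-geometry bounds matrix for a molecule
#'
#' A deterministic function of the heavy-atom topology (elements, bond
#' orders, formal charges) only -- never of the coordinates. Bonded pairs
#' are bracketed around the ideal bond length for the element pair and
#' order; 1-3 pairs around the chord implied by the ideal angle at the
#' central atom (law of cosines), with ring-interior angles for small and
#' aromatic rings; other pairs get a van der Waals contact lower bound
#' (scaled 0.8 for 1-4 pairs) and a loose upper bound. The matrices are
#' then triangle-smoothed.
#'
#' @param mol A [mol_pose()]; hydrogens are stripped internally.
#' @param radii A [radii_table()].
#' @return A list of class `bounds_matrix` with symmetric matrices `lower`
#'   and `upper` (Angstrom), `n` (heavy-atom count), and `graph_dist`
#'   (topological distances, used by the checks to classify pairs).
#' @export
bounds_matrix <- function(mol, radii = radii_table()) {
  heavy <- strip_hydrogens(mol)
  kek <- heavy
  # bonds of perceived-aromatic rings use the aromatic ideal length whether
  # the input was kekulised or marked aromatic
  pre_rings <- smallest_rings(kek)
  pre_arom <- perceive_aromatic_rings(kek, pre_rings)
  if (length(pre_arom) > 0) {
    bkey <- paste(pmin(kek$bonds$i, kek$bonds$j), pmax(kek$bonds$i, kek$bonds$j))
    for (r in pre_arom) {
      ring <- pre_rings[[r]]
      nr <- length(ring)
      rkey <- paste(pmin(ring, ring[c(2:nr, 1)]), pmax(ring, ring[c(2:nr, 1)]))
      kek$bonds$order[bkey %in% rkey] <- 4L
    }
  }
  n <- n_atoms(kek)
  l <- matrix(0, n, n); u <- matrix(UPPER_INIT, n, n)
  diag(u) <- 0
  set_pair <- function(i, j, lo, hi) {
    # union across multiple derivations for the same pair
    if (l[i, j] > 0 || u[i, j] < UPPER_INIT) {
      lo <- min(lo, l[i, j]); hi <- max(hi, u[i, j])
    }
    l[i, j] <<- lo; l[j, i] <<- lo
    u[i, j] <<- hi; u[j, i] <<- hi
  }
  b <- kek$bonds
  blen <- numeric(nrow(b))
  for (k in seq_len(nrow(b))) {
    blen[k] <- ideal_bond_length(kek$elements[b$i[k]], kek$elements[b$j[k]],
                                 b$order[k], radii)
    set_pair(b$i[k], b$j[k], blen[k] - BOND_TOL, blen[k] + BOND_TOL)
  }
  ideal_len <- matrix(NA_real_, n, n)
  ideal_len[cbind(b$i, b$j)] <- blen; ideal_len[cbind(b$j, b$i)] <- blen
  rings <- pre_rings
  arom <- pre_arom
  hyb <- hybridisation(kek)
  adj <- adjacency_list(kek)
  bo <- bond_order_matrix(kek)
  # ring membership of consecutive triples
  triple_ring <- function(i, j, k) {
    for (r in seq_along(rings)) {
      ring <- rings[[r]]
      if (all(c(i, j, k) %in% ring)) {
        nr <- length(ring)
        pj <- match(j, ring)
        nbrs <- ring[c((pj - 2) %% nr + 1, pj %% nr + 1)]
        if (all(c(i, k) %in% nbrs)) return(r)
      }
    }
    0L
  }
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    for (a in seq_len(length(nb) - 1)) for (bb in (a + 1):length(nb)) {
      i <- nb[a]; k <- nb[bb]
      if (bo[i, k] > 0) next  # three-membered ring: governed by the bond bound
      r <- triple_ring(i, j, k)
      if (r > 0) {
        nr <- length(rings[[r]])
        if (r %in% arom) {
          theta <- 180 * (nr - 2) / nr; tol <- 0.10
        } else if (nr == 4) { theta <- 90; tol <- 0.20 }
        else if (nr == 5) { theta <- 105; tol <- 0.25 }
        else { theta <- ideal_angle(kek$elements[j], hyb[j]); tol <- 0.15 }
      } else {
        theta <- ideal_angle(kek$elements[j], hyb[j])
        tol <- ANGLE_CHORD_TOL
      }
      d0 <- chord(ideal_len[i, j], ideal_len[j, k], theta)
      set_pair(i, k, d0 - tol, d0 + tol)
    }
  }
  # cross-ring chords in aromatic rings (regular polygon geometry)
  for (r in arom) {
    ring <- rings[[r]]
    nr <- length(ring)
    side <- mean(ideal_len[cbind(ring, ring[c(2:nr, 1)])])
    for (a in seq_len(nr - 1)) for (bb in (a + 1):nr) {
      i <- ring[a]; k <- ring[bb]
      sep <- min(abs(a - bb), nr - abs(a - bb))
      if (sep < 3) next
      d0 <- side * sin(sep * pi / nr) / sin(pi / nr)
      set_pair(i, k, d0 - RING_CHORD_TOL, d0 + RING_CHORD_TOL)
    }
  }
  # graph distances classify remaining pairs
  g <- igraph::graph_from_data_frame(
    data.frame(from = b$i, to = b$j), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  gd <- igraph::distances(g)
  gd <- gd[order(as.integer(rownames(gd))), order(as.integer(colnames(gd)))]
  vdw <- element_radius(kek$elements, "vdw", radii)
  for (i in seq_len(n - 1)) for (k in (i + 1):n) {
    if (l[i, k] > 0 || u[i, k] < UPPER_INIT) next
    contact <- vdw[i] + vdw[k]
    lo <- if (is.finite(gd[i, k]) && gd[i, k] == 3) NONBONDED_14_SCALE * contact else contact
    set_pair(i, k, lo, UPPER_INIT)
  }
  # triangle smoothing: uppers by Floyd-Warshall, lowers against uppers
  for (k in seq_len(n)) u <- pmin(u, outer(u[, k], u[k, ], "+"))
  for (k in seq_len(n)) {
    l <- pmax(l, outer(l[, k], u[k, ], "-"))
    l <- pmax(l, outer(u[k, ], l[, k], function(a, b) b - a))
  }
  l <- pmin(l, u)  # guard against inconsistent input topologies
  diag(l) <- 0
  structure(list(lower = l, upper = u, n = n, graph_dist = gd,
                 elements = kek$elements),
            class = "bounds_matrix")
}

#' @export
print.bounds_matrix <- function(x, ...) {
  cat(sprintf("<bounds_matrix> %d heavy atoms\n", x$n))
  invisible(x)
}
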