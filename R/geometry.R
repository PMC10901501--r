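# Intramolecular geometry checks: bond lengths, bond angles and internal
# clashes against the distance-geometry bounds matrix, and least-squares
# planarity of aromatic rings and acyclic C=C units.

heavy_dist <- function(xyz) as.matrix(stats::dist(xyz))

#' Bond length check
#'
#' Every bonded heavy-atom distance d must satisfy
#' (1 - tolerance) * lower <= d <= (1 + tolerance) * upper, with bounds
#' from the distance-geometry [bounds_matrix()].
#'
#' @param mol A [mol_pose()].
#' @param b A [bounds_matrix()] for `mol` (computed if missing).
#' @param tolerance Fractional tolerance on the bounds (default 0.25).
#' @return A [check_outcome()] named `"bond_lengths"`.
#' @export
check_bond_lengths <- function(mol, b = bounds_matrix(mol), tolerance = 0.25) {
  heavy <- strip_hydrogens(mol)
  d <- heavy_dist(heavy$xyz)
  det <- NULL
  for (k in seq_len(nrow(heavy$bonds))) {
    i <- heavy$bonds$i[k]; j <- heavy$bonds$j[k]
    lo <- (1 - tolerance) * b$lower[i, j]
    hi <- (1 + tolerance) * b$upper[i, j]
    if (d[i, j] < lo || d[i, j] > hi) {
      det <- rbind(det, detail_row(
        sprintf("bond %s%d-%s%d", heavy$elements[i], i, heavy$elements[j], j),
        d[i, j], lo, hi))
    }
  }
  check_outcome("bond_lengths", is.null(det), det)
}

#' Bond angle check
#'
#' Each bonded triple i-j-k is checked through its distance-geometry
#' surrogate: the 1-3 distance d(i,k) must satisfy
#' (1 - tolerance) * lower <= d <= (1 + tolerance) * upper.
#'
#' @inheritParams check_bond_lengths
#' @return A [check_outcome()] named `"bond_angles"`.
#' @export
check_bond_angles <- function(mol, b = bounds_matrix(mol), tolerance = 0.25) {
  heavy <- strip_hydrogens(mol)
  d <- heavy_dist(heavy$xyz)
  adj <- adjacency_list(heavy)
  bo <- bond_order_matrix(heavy)
  det <- NULL
  for (j in seq_len(n_atoms(heavy))) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    for (a in seq_len(length(nb) - 1)) for (bb in (a + 1):length(nb)) {
      i <- nb[a]; k <- nb[bb]
      if (bo[i, k] > 0) next  # three-ring: the bond bound governs
      lo <- (1 - tolerance) * b$lower[i, k]
      hi <- (1 + tolerance) * b$upper[i, k]
      if (d[i, k] < lo || d[i, k] > hi) {
        det <- rbind(det, detail_row(
          sprintf("angle %s%d-%s%d-%s%d (1-3 distance)",
                  heavy$elements[i], i, heavy$elements[j], j,
                  heavy$elements[k], k),
          d[i, k], lo, hi))
      }
    }
  }
  check_outcome("bond_angles", is.null(det), det)
}

#' Internal steric clash check
#'
#' Heavy-atom pairs that are neither bonded (1-2) nor angle-related (1-3)
#' must keep a distance above (1 - tolerance) times the distance-geometry
#' lower bound (default tolerance 0.30, i.e. 0.7 * lower).
#'
#' @inheritParams check_bond_lengths
#' @param tolerance Fractional tolerance (default 0.30).
#' @return A [check_outcome()] named `"internal_steric_clash"`.
#' @export
check_internal_clash <- function(mol, b = bounds_matrix(mol), tolerance = 0.30) {
  heavy <- strip_hydrogens(mol)
  d <- heavy_dist(heavy$xyz)
  n <- n_atoms(heavy)
  det <- NULL
  for (i in seq_len(max(0, n - 1))) for (k in (i + 1):n) {
    if (!is.finite(b$graph_dist[i, k]) || b$graph_dist[i, k] >= 3) {
      lo <- (1 - tolerance) * b$lower[i, k]
      if (d[i, k] < lo) {
        det <- rbind(det, detail_row(
          sprintf("non-bonded pair %s%d...%s%d",
                  heavy$elements[i], i, heavy$elements[k], k),
          d[i, k], lo, NA_real_))
      }
    }
  }
  check_outcome("internal_steric_clash", is.null(det), det)
}

#' Least-squares plane fit
#'
#' Fits the plane minimising the sum of squared perpendicular distances
#' (via singular value decomposition of the centred coordinates) and
#' reports the maximum absolute deviation. Collinear and otherwise
#' degenerate point sets are contained in some plane exactly, so their
#' deviation is 0.
#'
#' @param points Numeric matrix, one row per point, 3 columns.
#' @return List with `normal` (unit vector), `offset` (plane constant:
#'   points x satisfy normal . x = offset), `max_dev` (Angstrom).
#' @export
fit_plane <- function(points) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 3) stop("plane fit needs at least 3 points")
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr))
  normal <- sv$v[, 3]
  dev <- as.numeric(sweep(points, 2, ctr) %*% normal)
  list(normal = normal, offset = sum(normal * ctr), max_dev = max(abs(dev)))
}

#' Aromatic ring planarity check
#'
#' Every aromatic ring with 5 or 6 members must have all ring atoms within
#' `threshold` of its own least-squares plane. Fused systems are tested
#' ring by ring.
#'
#' @param mol A [mol_pose()].
#' @param threshold Maximum allowed deviation in Angstrom (default 0.25).
#' @return A [check_outcome()] named `"planar_aromatic_rings"`.
#' @export
check_ring_planarity <- function(mol, threshold = 0.25) {
  heavy <- strip_hydrogens(mol)
  rings <- smallest_rings(heavy)
  arom <- perceive_aromatic_rings(heavy, rings)
  det <- NULL
  for (r in arom) {
    ring <- rings[[r]]
    if (!(length(ring) %in% c(5, 6))) next
    fp <- fit_plane(heavy$xyz[ring, , drop = FALSE])
    if (fp$max_dev > threshold) {
      det <- rbind(det, detail_row(
        sprintf("aromatic ring [%s]", paste(ring, collapse = ",")),
        fp$max_dev, NA_real_, threshold))
    }
  }
  check_outcome("planar_aromatic_rings", is.null(det), det)
}

#' Aliphatic double bond planarity check
#'
#' For each non-ring, non-aromatic carbon-carbon double bond, the two
#' carbons and their heavy-atom neighbours (at most four) must lie within
#' `threshold` of one shared least-squares plane.
#'
#' @inheritParams check_ring_planarity
#' @return A [check_outcome()] named `"planar_double_bonds"`.
#' @export
check_double_bond_planarity <- function(mol, threshold = 0.25) {
  heavy <- strip_hydrogens(mol)
  rings <- smallest_rings(heavy)
  ring_atoms <- unique(unlist(rings))
  adj <- adjacency_list(heavy)
  det <- NULL
  b <- heavy$bonds
  for (k in which(b$order == 2L)) {
    i <- b$i[k]; j <- b$j[k]
    if (heavy$elements[i] != "C" || heavy$elements[j] != "C") next
    in_ring <- any(vapply(rings, function(r) all(c(i, j) %in% r), TRUE))
    if (in_ring) next
    group <- unique(c(i, j, adj[[i]], adj[[j]]))
    if (length(group) < 3) next
    fp <- fit_plane(heavy$xyz[group, , drop = FALSE])
    if (fp$max_dev > threshold) {
      det <- rbind(det, detail_row(
        sprintf("C=C unit %d=%d with neighbours", i, j),
        fp$max_dev, NA_real_, threshold))
    }
  }
  check_outcome("planar_double_bonds", is.null(det), det)
}
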