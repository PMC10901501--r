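#' @title Molecule pose objects
#'
#' @description A `mol_pose` holds one small molecule with its elements,
#' formal charges, isotope labels, bond graph and a single 3D conformation
#' in Angstrom. It is the unit every validity check consumes.
#'
#' @name mol_pose
NULL

#' Construct a molecule pose
#'
#' @param elements Character vector of element symbols.
#' @param xyz Numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param bonds Data frame with integer columns `i`, `j` (1-based atom
#'   indices) and `order` (1, 2, 3, or 4 for aromatic).
#' @param charges Integer vector of formal charges (default all 0).
#' @param isotopes Integer vector of isotope mass labels, 0 = natural.
#' @param name Text identifier.
#' @param source_index Ordinal of the record in its source file.
#' @return An object of class `mol_pose`.
#' @export
mol_pose <- function(elements, xyz, bonds,
                     charges = integer(length(elements)),
                     isotopes = integer(length(elements)),
                     name = "", source_index = NA_integer_) {
  n <- length(elements)
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) == 0) bonds <- data.frame(i = integer(), j = integer(), order = integer())
  names(bonds)[1:3] <- c("i", "j", "order")
  bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
  bonds$order <- as.integer(bonds$order)
  if (nrow(xyz) != n) stop("xyz must have one row per atom")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (nrow(bonds) > 0) {
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
      stop("bond references non-existent atom")
    if (any(bonds$i == bonds$j)) stop("self-bond")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bond")
    if (!all(bonds$order %in% 1:4)) stop("bond order must be 1, 2, 3 or 4 (aromatic)")
  }
  if (!any(elements != "H")) stop("molecule has no heavy atom")
  structure(list(
    elements = as.character(elements), xyz = xyz, bonds = bonds,
    charges = as.integer(charges), isotopes = as.integer(isotopes),
    name = as.character(name), source_index = as.integer(source_index)
  ), class = "mol_pose")
}

#' @export
print.mol_pose <- function(x, ...) {
  nh <- sum(x$elements != "H")
  cat(sprintf("<mol_pose> %s: %d atoms (%d heavy), %d bonds, net charge %+d\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              length(x$elements), nh, nrow(x$bonds), sum(x$charges)))
  invisible(x)
}

n_atoms <- function(mol) length(mol$elements)

is_heavy <- function(mol) mol$elements != "H"

#' Strip hydrogens from a pose
#'
#' Geometric checks are calibrated on heavy atoms; this drops all H atoms
#' and their bonds, recording on each heavy atom how many hydrogens it
#' carried (`$h_count`), which the valence and kekulisation logic uses.
#'
#' @param mol A [mol_pose()].
#' @return A heavy-atom-only `mol_pose` with an `h_count` field.
#' @export
strip_hydrogens <- function(mol) {
  keep <- which(is_heavy(mol))
  if (length(keep) == n_atoms(mol)) {
    mol$h_count <- explicit_h_counts(mol)[keep]
    return(mol)
  }
  hmap <- match(seq_len(n_atoms(mol)), keep)
  hc <- explicit_h_counts(mol)
  b <- mol$bonds
  bkeep <- !is.na(hmap[b$i]) & !is.na(hmap[b$j])
  b <- b[bkeep, , drop = FALSE]
  b$i <- hmap[b$i]; b$j <- hmap[b$j]
  out <- mol_pose(mol$elements[keep], mol$xyz[keep, , drop = FALSE], b,
                  mol$charges[keep], mol$isotopes[keep], mol$name, mol$source_index)
  out$h_count <- hc[keep]
  out
}

# number of explicit hydrogen neighbours per atom
explicit_h_counts <- function(mol) {
  hc <- integer(n_atoms(mol))
  b <- mol$bonds
  if (nrow(b) > 0) {
    ih <- mol$elements[b$i] == "H"
    jh <- mol$elements[b$j] == "H"
    for (k in which(jh & !ih)) hc[b$i[k]] <- hc[b$i[k]] + 1L
    for (k in which(ih & !jh)) hc[b$j[k]] <- hc[b$j[k]] + 1L
  }
  hc
}

#' Apply a rigid transformation or atom reordering to a pose
#'
#' @param mol A [mol_pose()].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric offset in Angstrom.
#' @return The transformed pose.
#' @export
transform_pose <- function(mol, rotation = diag(3), translation = c(0, 0, 0)) {
  mol$xyz <- mol$xyz %*% t(rotation) + matrix(translation, n_atoms(mol), 3, byrow = TRUE)
  mol
}

# reorder atoms by permutation perm (new order = old indices perm)
reindex_pose <- function(mol, perm) {
  inv <- match(seq_along(perm), perm)
  b <- mol$bonds
  b$i <- inv[b$i]; b$j <- inv[b$j]
  mol_pose(mol$elements[perm], mol$xyz[perm, , drop = FALSE], b,
           mol$charges[perm], mol$isotopes[perm], mol$name, mol$source_index)
}
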