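# Intermolecular checks: minimum-distance ratios and volume-overlap shares
# of the ligand against the protein and its organic/inorganic cofactors.

#' Atom set
#'
#' Heavy atoms only: elements plus coordinates and a role label.
#'
#' @param elements Character vector of element symbols.
#' @param xyz Numeric matrix of coordinates (Angstrom).
#' @param role One of `"ligand"`, `"protein"`, `"organic_cofactor"`,
#'   `"inorganic_cofactor"`.
#' @return An object of class `atom_set`.
#' @export
atom_set <- function(elements, xyz,
                     role = c("ligand", "protein", "organic_cofactor",
                              "inorganic_cofactor")) {
  role <- match.arg(role)
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  keep <- elements != "H"
  structure(list(elements = as.character(elements[keep]),
                 xyz = xyz[keep, , drop = FALSE], role = role),
            class = "atom_set")
}

#' Coerce a molecule pose to a heavy-atom set
#' @param mol A [mol_pose()].
#' @param role Role label for the set.
#' @return An [atom_set()].
#' @export
as_atom_set <- function(mol, role = "ligand") {
  atom_set(mol$elements, mol$xyz, role)
}

#' Minimum pairwise distance ratio between two atom sets
#'
#' For every heavy-atom pair the ratio d(i,j) / (r_i + r_j) is formed with
#' the chosen radius kind; the minimum over all pairs is returned together
#' with the attaining pair. The clash check passes when this minimum
#' exceeds 0.75.
#'
#' @param ligand,other [atom_set()]s; `other` may be empty (ratio `Inf`).
#' @param radii A [radii_table()].
#' @param radius_kind `"vdw"` (protein, organic cofactors) or
#'   `"covalent"` (inorganic cofactors).
#' @return List with `min_ratio`, `pair` (indices into ligand/other), and
#'   `distance`.
#' @export
min_distance_ratio <- function(ligand, other, radii = radii_table(),
                               radius_kind = c("vdw", "covalent")) {
  radius_kind <- match.arg(radius_kind)
  if (length(ligand$elements) == 0) stop("empty ligand atom set")
  if (length(other$elements) == 0) {
    return(list(min_ratio = Inf, pair = c(NA_integer_, NA_integer_),
                distance = NA_real_))
  }
  rl <- element_radius(ligand$elements, radius_kind, radii)
  ro <- element_radius(other$elements, radius_kind, radii)
  d <- outer(rowSums(ligand$xyz^2), rowSums(other$xyz^2), "+") -
    2 * ligand$xyz %*% t(other$xyz)
  d <- sqrt(pmax(d, 0))
  ratio <- d / outer(rl, ro, "+")
  k <- arrayInd(which.min(ratio), dim(ratio))
  list(min_ratio = min(ratio), pair = as.integer(k),
       distance = d[k])
}

#' Share of ligand volume overlapping another atom set
#'
#' Each body is the union of spheres of radius `radius_scale` times the
#' van der Waals radius around its heavy atoms. The share
#' vol(L intersect O) / vol(L) is integrated on an axis-aligned grid over
#' the ligand bounding box (default spacing 0.25 Angstrom resolves the
#' 7.5% threshold to within about 2% relative accuracy; see the two-sphere
#' lens oracle in the test suite).
#'
#' @inheritParams min_distance_ratio
#' @param radius_scale Scale factor on the van der Waals radii (0.8 for
#'   protein/organic, 0.5 for inorganic).
#' @param spacing Grid spacing in Angstrom.
#' @return Overlap share in `[0, 1]`.
#' @export
volume_overlap_share <- function(ligand, other, radii = radii_table(),
                                 radius_scale = 0.8, spacing = 0.25) {
  if (length(ligand$elements) == 0) stop("empty ligand atom set")
  if (length(other$elements) == 0) return(0)
  rl <- element_radius(ligand$elements, "vdw", radii) * radius_scale
  ro <- element_radius(other$elements, "vdw", radii) * radius_scale
  lo <- apply(ligand$xyz - rl, 2, min) - spacing / 2
  hi <- apply(ligand$xyz + rl, 2, max) + spacing / 2
  gx <- seq(lo[1] + spacing / 2, hi[1], by = spacing)
  gy <- seq(lo[2] + spacing / 2, hi[2], by = spacing)
  gz <- seq(lo[3] + spacing / 2, hi[3], by = spacing)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  inside <- function(xyz, r) {
    ok <- rep(FALSE, nrow(pts))
    for (a in seq_len(nrow(xyz))) {
      da <- (pts[, 1] - xyz[a, 1])^2 + (pts[, 2] - xyz[a, 2])^2 +
        (pts[, 3] - xyz[a, 3])^2
      ok <- ok | (da <= r[a]^2)
    }
    ok
  }
  in_l <- inside(ligand$xyz, rl)
  vl <- sum(in_l)
  if (vl == 0) return(0)
  # only other-atoms whose sphere can reach the ligand body contribute
  dmin <- apply(other$xyz, 1, function(p) {
    min(sqrt(rowSums(sweep(ligand$xyz, 2, p)^2)) - rl)
  })
  near <- dmin <= ro
  if (!any(near)) return(0)
  in_o <- inside(other$xyz[near, , drop = FALSE], ro[near])
  sum(in_l & in_o) / vl
}

#' Run the six intermolecular checks for one ligand pose
#'
#' Distance checks use the 0.75 factor (van der Waals radii for protein
#' and organic cofactors, covalent radii for inorganic cofactors); volume
#' overlap checks use the 7.5% threshold with radius scale 0.8 for
#' protein/organic and 0.5 for inorganic. Cofactor groups should already
#' be restricted to those near the ligand (see [cofactors_near_ligand()]).
#' Checks against an empty partner pass vacuously.
#'
#' @param ligand An [atom_set()] (or [mol_pose()]) for the pose.
#' @param receptor A [load_receptor()] result, with cofactor groups
#'   already filtered for proximity.
#' @param radii A [radii_table()].
#' @param distance_factor Minimum allowed distance ratio (default 0.75).
#' @param overlap_threshold Maximum allowed overlap share (default 0.075).
#' @param scale_organic,scale_inorganic Radius scales for the overlap
#'   checks (defaults 0.8 and 0.5).
#' @param spacing Overlap grid spacing (Angstrom).
#' @return Named list of six [check_outcome()]s in report order.
#' @export
run_intermolecular_checks <- function(ligand, receptor, radii = radii_table(),
                                      distance_factor = 0.75,
                                      overlap_threshold = 0.075,
                                      scale_organic = 0.8,
                                      scale_inorganic = 0.5,
                                      spacing = 0.25) {
  if (inherits(ligand, "mol_pose")) ligand <- as_atom_set(ligand)
  prot <- atom_set(receptor$protein_atoms$element,
                   as.matrix(receptor$protein_atoms[, c("x", "y", "z")]),
                   "protein")
  merge_groups <- function(groups, role) {
    if (length(groups) == 0) {
      return(atom_set(character(), matrix(numeric(), 0, 3), role))
    }
    el <- unlist(lapply(groups, function(g) g$element))
    xyz <- do.call(rbind, lapply(groups, function(g) as.matrix(g[, c("x", "y", "z")])))
    atom_set(el, xyz, role)
  }
  org <- merge_groups(receptor$organic_cofactors, "organic_cofactor")
  inorg <- merge_groups(receptor$inorganic_cofactors, "inorganic_cofactor")
  dist_check <- function(nm, other, kind) {
    res <- min_distance_ratio(ligand, other, radii, kind)
    if (!is.finite(res$min_ratio)) {
      return(check_outcome(nm, TRUE,
        detail_row("no partner atoms: passes vacuously", NA_real_)))
    }
    det <- detail_row(sprintf("minimum distance ratio (%s radii)", kind),
                      res$min_ratio, distance_factor, NA_real_)
    check_outcome(nm, res$min_ratio > distance_factor, det)
  }
  ovl_check <- function(nm, other, scale) {
    if (length(other$elements) == 0) {
      return(check_outcome(nm, TRUE,
        detail_row("no partner atoms: passes vacuously", 0)))
    }
    share <- volume_overlap_share(ligand, other, radii, scale, spacing)
    det <- detail_row(sprintf("ligand volume overlap share (scale %.1f)", scale),
                      share, NA_real_, overlap_threshold)
    check_outcome(nm, share < overlap_threshold, det)
  }
  list(
    min_protein_ligand_distance = dist_check("min_protein_ligand_distance", prot, "vdw"),
    min_distance_organic_cofactors = dist_check("min_distance_organic_cofactors", org, "vdw"),
    min_distance_inorganic_cofactors = dist_check("min_distance_inorganic_cofactors", inorg, "covalent"),
    volume_overlap_protein = ovl_check("volume_overlap_protein", prot, scale_organic),
    volume_overlap_organic_cofactors = ovl_check("volume_overlap_organic_cofactors", org, scale_organic),
    volume_overlap_inorganic_cofactors = ovl_check("volume_overlap_inorganic_cofactors", inorg, scale_inorganic)
  )
}
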