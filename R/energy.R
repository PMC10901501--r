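# Conformation energy check: the pose's UFF single-point energy is
# compared against the mean energy of an ensemble of distance-geometry
# embedded, force-field relaxed conformations generated from topology
# alone. Embedding is the classic metric-matrix method driven by the same
# bounds matrix as the geometry checks; energies and relaxation go through
# the Open Babel UFF implementation.

#' Embed one conformer from the distance-geometry bounds
#'
#' Samples a random distance matrix between the smoothed bounds, converts
#' it to a metric (Gram) matrix and takes the top three eigenvectors as 3D
#' coordinates. The raw embedding is crude by construction and is intended
#' to be followed by force-field relaxation.
#'
#' @param mol A [mol_pose()]; coordinates are ignored, topology only.
#' @param b A [bounds_matrix()] for `mol`.
#' @return A heavy-atom [mol_pose()] with embedded coordinates.
#' @export
embed_conformer <- function(mol, b = bounds_matrix(mol)) {
  n <- b$n
  lo <- b$lower; hi <- pmin(b$upper, 2 * max(b$lower) + 5)
  w <- matrix(stats::runif(n * n), n, n)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  D2 <- (lo + w * (hi - lo))^2
  diag(D2) <- 0
  rm2 <- rowMeans(D2)
  d0 <- rm2 - sum(D2) / (2 * n^2)
  G <- (outer(d0, d0, "+") - D2) / 2
  ev <- eigen(G, symmetric = TRUE)
  lam <- pmax(ev$values[1:3], 0)
  xyz <- ev$vectors[, 1:3, drop = FALSE] %*% diag(sqrt(lam), 3)
  # break exact planarity: a perfectly flat embedding has zero
  # out-of-plane gradient by symmetry and traps the force-field relaxation
  xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = 0.02), nrow(xyz), 3)
  heavy <- strip_hydrogens(mol)
  heavy$xyz <- refine_embedding(xyz, b)
  heavy
}

# worst residual bound violation (Angstrom) of coordinates against bounds
embedding_violation <- function(xyz, b) {
  d <- as.matrix(stats::dist(xyz))
  up <- b$upper
  up[up > 100] <- Inf
  max(pmax(d - up, 0), pmax(b$lower - d, 0))
}

# embed with resampling: tangled metric-matrix draws happen; retry until
# the refined embedding respects the bounds to within `tol`
embed_conformer_retry <- function(mol, b, attempts = 8, tol = 0.3) {
  best <- NULL; best_v <- Inf
  for (a in seq_len(attempts)) {
    m <- embed_conformer(mol, b)
    v <- embedding_violation(m$xyz, b)
    if (v < best_v) { best <- m; best_v <- v }
    if (best_v < tol) break
  }
  best
}

# Gradient refinement of raw embedded coordinates against the bounds:
# quadratic penalty on violated lower/upper bounds. Untangles the crude
# metric-matrix output before force-field relaxation takes over.
refine_embedding <- function(xyz, b, iters = 200, step = 0.05) {
  n <- nrow(xyz)
  if (n < 2) return(xyz)
  up <- b$upper
  up[up > 100] <- Inf  # leave unconstrained long-range pairs alone
  for (it in seq_len(iters)) {
    d <- as.matrix(stats::dist(xyz))
    diag(d) <- 1
    viol_hi <- pmax(d - up, 0)
    viol_lo <- pmax(b$lower - d, 0)
    if (max(viol_hi) < 1e-3 && max(viol_lo) < 1e-3) break
    coef <- (viol_hi - viol_lo) / d  # >0 pull together, <0 push apart
    diag(coef) <- 0
    grad <- xyz * rowSums(coef) - coef %*% xyz
    xyz <- xyz - step * grad
  }
  xyz
}

#' Conformer ensemble energies
#'
#' Generates `n` distance-geometry embedded conformations, completes their
#' hydrogens, relaxes each under the UFF for up to `max_relax_iterations`
#' conjugate-gradient steps, and records the relaxed single-point
#' energies. The ensemble depends only on the molecular topology and the
#' seed, never on the input coordinates.
#'
#' @param mol A [mol_pose()].
#' @param n Number of conformations to request (default 50).
#' @param max_relax_iterations Relaxation step cap (default 200).
#' @param seed Integer seed; the same seed yields identical energies.
#' @return An object of class `energy_ensemble`: list with `energies`
#'   (kcal/mol, one per converged conformer), `n_requested`,
#'   `n_converged`, `seed`, and `mols` (the relaxed conformers, hydrogens
#'   included).
#' @export
conformer_ensemble <- function(mol, n = 50, max_relax_iterations = 200, seed = 1L) {
  out <- structure(list(energies = numeric(), n_requested = as.integer(n),
                        n_converged = 0L, seed = as.integer(seed),
                        mols = list()),
                   class = "energy_ensemble")
  if (n < 1) return(out)
  b <- tryCatch(bounds_matrix(mol), error = function(e) NULL)
  if (is.null(b)) return(out)
  embeds <- withr_seed(seed, {
    lapply(seq_len(n), function(k) embed_conformer_retry(mol, b))
  })
  ok <- vapply(embeds, function(m) all(is.finite(m$xyz)), TRUE)
  embeds <- embeds[ok]
  if (length(embeds) == 0) return(out)
  res <- tryCatch({
    withH <- ob_add_hydrogens_batch(embeds)
    relaxed <- ob_minimize(withH, steps = max_relax_iterations)
    energies <- ob_energies(relaxed)
    probe <- ob_minimize(relaxed, steps = 50)
    list(energies = energies, mols = relaxed,
         probe_energies = ob_energies(probe))
  }, error = function(e) NULL)
  if (is.null(res)) return(out)
  # a member counts as converged only if (a) relaxation untangled it --
  # the relaxed geometry satisfies its own distance-geometry bounds --
  # and (b) it reached a minimum: a short further relaxation probe leaves
  # its energy essentially unchanged
  geom_ok <- vapply(res$mols, function(m) {
    isTRUE(outcome_passed(check_bond_lengths(m, b)) &&
           outcome_passed(check_bond_angles(m, b)) &&
           outcome_passed(check_internal_clash(m, b)))
  }, TRUE)
  settled <- (res$energies - res$probe_energies) <=
    pmax(2, 0.25 * abs(res$energies))
  conv <- geom_ok & settled
  out$energies <- res$energies[conv]
  out$n_converged <- sum(conv)
  out$mols <- res$mols[conv]
  out
}

# run expr with a local RNG state
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

ob_add_hydrogens_batch <- function(mols) {
  require_openbabel()
  tf <- tempfile(fileext = ".sdf"); to <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(tf, to)))
  write_sdf(mols, tf)
  ob_run("obabel", c(tf, "-O", to, "-h"))
  out <- load_ligands(to)
  if (length(out$poses) != length(mols)) stop("hydrogen addition failed")
  out$poses
}

#' UFF single-point energy of a pose
#'
#' Hydrogens are completed (geometric placement on open valences; explicit
#' hydrogens are kept as given) because force-field energies require full
#' valences, then the universal force field energy (bond, angle, torsion,
#' inversion and van der Waals terms) is evaluated at the given
#' coordinates.
#'
#' @param mol A [mol_pose()].
#' @return Energy in kcal/mol.
#' @export
pose_energy <- function(mol) {
  withH <- ob_add_hydrogens_batch(list(mol))[[1]]
  ob_energies(withH)[1]
}

#' Energy ratio check
#'
#' The pose's UFF energy divided by the mean ensemble energy must not
#' exceed `threshold` (default 100; 7 reproduces the stricter published
#' calibration). A non-positive or near-zero ensemble mean is floored at
#' `epsilon` and flagged in the details.
#'
#' @param mol The pose under test.
#' @param ensemble An [conformer_ensemble()] result for the same topology.
#' @param threshold Maximum allowed ratio (default 100).
#' @param epsilon Denominator floor in kcal/mol (default 0.01).
#' @return A [check_outcome()] named `"energy_ratio"`.
#' @export
check_energy_ratio <- function(mol, ensemble, threshold = 100, epsilon = 0.01) {
  if (ensemble$n_converged < 1) {
    return(check_outcome("energy_ratio", NA,
      detail_row("no converged ensemble conformer (inconclusive)", NA_real_)))
  }
  e_pose <- tryCatch(pose_energy(mol), error = function(e) NA_real_)
  if (is.na(e_pose)) {
    return(check_outcome("energy_ratio", NA,
      detail_row("pose energy unavailable (inconclusive)", NA_real_)))
  }
  mu <- mean(ensemble$energies)
  floored <- mu < epsilon
  ratio <- e_pose / max(mu, epsilon)
  det <- detail_row(
    if (floored) sprintf("energy ratio (mean %.3f kcal/mol floored at %g)", mu, epsilon)
    else "energy ratio pose/ensemble-mean",
    ratio, NA_real_, threshold)
  check_outcome("energy_ratio", ratio <= threshold, det)
}
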