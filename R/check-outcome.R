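#' Check outcomes
#'
#' Every validity test returns a `check_outcome`: a name, a pass/fail flag
#' and a detail table of the measurements behind the verdict. A failing
#' outcome always lists at least one violating measurement.
#'
#' @param name Test name (snake-cased, fixed vocabulary; see
#'   [check_names()]).
#' @param passed Logical; `NA` marks an inconclusive failure (an internal
#'   error prevented the measurement -- treated as a failure in the
#'   aggregate verdict but distinguishable in reports).
#' @param details Data frame with columns `description`, `value`, `lower`,
#'   `upper` (allowed range; NA where not applicable).
#' @return An object of class `check_outcome`.
#' @export
check_outcome <- function(name, passed, details = NULL) {
  if (is.null(details)) {
    details <- data.frame(description = character(), value = numeric(),
                          lower = numeric(), upper = numeric())
  }
  if (isFALSE(passed) && nrow(details) == 0) {
    stop("a failing outcome must list at least one violating measurement")
  }
  structure(list(name = name, passed = passed, details = details),
            class = "check_outcome")
}

#' @export
print.check_outcome <- function(x, ...) {
  verdict <- if (isTRUE(x$passed)) "PASS" else if (isFALSE(x$passed)) "FAIL" else "INCONCLUSIVE"
  cat(sprintf("[%s] %s\n", verdict, x$name))
  if (nrow(x$details) > 0 && !isTRUE(x$passed)) {
    print(utils::head(x$details, 5), row.names = FALSE)
  }
  invisible(x)
}

#' Did a check pass?
#'
#' `TRUE` only for an outright pass; inconclusive (`NA`) counts as not
#' passed.
#'
#' @param x A [check_outcome()].
#' @return Logical scalar.
#' @export
outcome_passed <- function(x) isTRUE(x$passed)

detail_row <- function(description, value, lower = NA_real_, upper = NA_real_) {
  data.frame(description = description, value = value,
             lower = lower, upper = upper, stringsAsFactors = FALSE)
}

#' Names of the pose validity checks in report order
#'
#' The fixed ordering used in reports and waterfall summaries: six chemical
#' validity and consistency checks, six intramolecular checks, six
#' intermolecular checks.
#'
#' @return Character vector of the 18 check names.
#' @export
check_names <- function() {
  c("file_loads", "sanitisation", "molecular_formula", "bonds",
    "tetrahedral_chirality", "double_bond_stereochemistry",
    "bond_lengths", "bond_angles", "planar_aromatic_rings",
    "planar_double_bonds", "internal_steric_clash", "energy_ratio",
    "min_protein_ligand_distance", "min_distance_organic_cofactors",
    "min_distance_inorganic_cofactors", "volume_overlap_protein",
    "volume_overlap_organic_cofactors", "volume_overlap_inorganic_cofactors")
}
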