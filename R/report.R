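# Orchestration: run every applicable check on each predicted pose,
# aggregate the overall validity verdict, and summarise batches as
# waterfall counts (first-failure attribution in fixed report order).

#' Default configuration of all check thresholds
#'
#' Every tunable threshold of the suite with its default:
#' bounds tolerances 0.25 (bonds/angles) and 0.30 (non-bonded clash),
#' planarity 0.25 Angstrom, energy ratio 100 from a 50-conformer ensemble
#' relaxed up to 200 iterations, intermolecular distance factor 0.75,
#' volume overlap threshold 7.5% with radius scales 0.8 (protein/organic)
#' and 0.5 (inorganic), cofactor proximity cutoff 4.0 Angstrom, RMSD
#' coverage threshold 2.0 Angstrom.
#'
#' @param ... Named overrides of individual defaults.
#' @return Named list of thresholds.
#' @export
poseval_config <- function(...) {
  cfg <- list(
    bond_tolerance = 0.25,
    angle_tolerance = 0.25,
    clash_tolerance = 0.30,
    planarity_threshold = 0.25,
    energy_ratio_threshold = 100,
    ensemble_size = 50,
    relax_iterations = 200,
    distance_factor = 0.75,
    overlap_threshold = 0.075,
    overlap_scale_organic = 0.8,
    overlap_scale_inorganic = 0.5,
    cofactor_cutoff = 4.0,
    rmsd_threshold = 2.0,
    overlap_grid_spacing = 0.25,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read a key-value configuration file
#'
#' Plain `key = value` lines (comments with `#`); keys as in
#' [poseval_config()].
#'
#' @param path File path.
#' @return A full config list with the file's overrides applied.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- lines[grepl("=", lines)]
  kv <- strsplit(lines, "=")
  over <- stats::setNames(
    lapply(kv, function(p) as.numeric(trimws(p[2]))),
    vapply(kv, function(p) trimws(p[1]), ""))
  do.call(poseval_config, over)
}

#' Applicable check subset for a run mode
#'
#' `mol` runs loadability, sanitisation, the intramolecular geometry
#' checks and the energy ratio; `dock` adds the six intermolecular checks;
#' `full` adds the four consistency checks against the true ligand (and
#' RMSD is reported).
#'
#' @param mode `"full"`, `"dock"` or `"mol"`.
#' @return Character vector of applicable check names in report order.
#' @export
run_modes <- function(mode = c("full", "dock", "mol")) {
  mode <- match.arg(mode)
  all <- check_names()
  intra <- c("file_loads", "sanitisation", "bond_lengths", "bond_angles",
             "planar_aromatic_rings", "planar_double_bonds",
             "internal_steric_clash", "energy_ratio")
  inter <- c("min_protein_ligand_distance", "min_distance_organic_cofactors",
             "min_distance_inorganic_cofactors", "volume_overlap_protein",
             "volume_overlap_organic_cofactors", "volume_overlap_inorganic_cofactors")
  sel <- switch(mode, mol = intra, dock = c(intra, inter), full = all)
  all[all %in% sel]
}

#' Run the full validity suite on a file of predicted poses
#'
#' For each record of the predicted-poses SDF: loadability, sanitisation,
#' chemical consistency against the true ligand(s), intramolecular
#' geometry and energy-ratio checks, intermolecular checks against the
#' receptor and its 4.0-Angstrom-proximal cofactors, and symmetry-aware
#' RMSD against all true copies. Per-pose failures are recorded in the
#' row, never aborting the batch. Conformer ensembles are cached per
#' topology within the call.
#'
#' @param pred_sdf Path to the predicted (re-docked) ligand SDF.
#' @param true_sdf Path to the reference ligand SDF (required for
#'   `mode = "full"`).
#' @param receptor_pdb Path to the receptor PDB (required for `full` and
#'   `dock`).
#' @param mode See [run_modes()].
#' @param config A [poseval_config()].
#' @return A list of class `bust_result`: one row per record, each a list
#'   with `pose`, `name`, `outcomes` (named [check_outcome()]s; missing
#'   entries are inapplicable), `rmsd`, `rmsd_within_threshold`,
#'   `pose_valid` (conjunction over applicable checks).
#' @export
bust <- function(pred_sdf, true_sdf = NULL, receptor_pdb = NULL,
                 mode = c("full", "dock", "mol"), config = poseval_config()) {
  mode <- match.arg(mode)
  if (mode == "full" && (is.null(true_sdf) || is.null(receptor_pdb)))
    stop("full mode needs predicted poses, true ligand(s) and a receptor")
  if (mode == "dock" && is.null(receptor_pdb))
    stop("dock mode needs predicted poses and a receptor")
  applicable <- run_modes(mode)
  pred <- load_ligands(pred_sdf)
  true_mols <- if (!is.null(true_sdf)) load_ligands(true_sdf)$poses else list()
  receptor <- if (!is.null(receptor_pdb)) load_receptor(receptor_pdb) else NULL
  ens_cache <- new.env()
  rows <- list()
  pose_i <- 0L
  for (k in seq_len(nrow(pred$status))) {
    st <- pred$status[k, ]
    if (!st$loaded) {
      outcomes <- list(file_loads = check_outcome(
        "file_loads", FALSE, detail_row(st$reason, NA_real_)))
      rows[[k]] <- bust_row(st$name, NULL, outcomes, applicable,
                            NA_real_, NA, config)
      next
    }
    pose_i <- pose_i + 1L
    pose <- pred$poses[[pose_i]]
    rows[[k]] <- bust_pose(pose, true_mols, receptor, mode, applicable,
                           config, ens_cache)
  }
  structure(rows, class = "bust_result", mode = mode)
}

#' Run the validity suite on one in-memory pose
#'
#' The single-pose core of [bust()]; useful programmatically.
#'
#' @param pose A [mol_pose()].
#' @param true_mols List of reference copies (may be empty outside full
#'   mode).
#' @param receptor A [load_receptor()] result or `NULL`.
#' @param mode,config As in [bust()].
#' @param applicable Check subset (defaults to `run_modes(mode)`).
#' @param ens_cache Internal ensemble cache environment.
#' @return A single bust row (see [bust()]).
#' @export
bust_pose <- function(pose, true_mols = list(), receptor = NULL,
                      mode = "full", applicable = run_modes(mode),
                      config = poseval_config(), ens_cache = new.env()) {
  outcomes <- list(file_loads = check_outcome("file_loads", TRUE))
  outcomes$sanitisation <- check_sanitises(pose)
  if ("molecular_formula" %in% applicable && length(true_mols) > 0) {
    outcomes <- c(outcomes, compare_consistency(pose, true_mols[[1]]))
  }
  b <- tryCatch(bounds_matrix(pose), error = function(e) NULL)
  if (!is.null(b)) {
    outcomes$bond_lengths <- check_bond_lengths(pose, b, config$bond_tolerance)
    outcomes$bond_angles <- check_bond_angles(pose, b, config$angle_tolerance)
    outcomes$planar_aromatic_rings <-
      check_ring_planarity(pose, config$planarity_threshold)
    outcomes$planar_double_bonds <-
      check_double_bond_planarity(pose, config$planarity_threshold)
    outcomes$internal_steric_clash <-
      check_internal_clash(pose, b, config$clash_tolerance)
  } else {
    for (nm in c("bond_lengths", "bond_angles", "planar_aromatic_rings",
                 "planar_double_bonds", "internal_steric_clash")) {
      outcomes[[nm]] <- check_outcome(nm, NA,
        detail_row("bounds matrix unavailable (inconclusive)", NA_real_))
    }
  }
  if ("energy_ratio" %in% applicable) {
    key <- topology_key(pose)
    ens <- ens_cache[[key]]
    if (is.null(ens)) {
      ens <- conformer_ensemble(pose, n = config$ensemble_size,
                                max_relax_iterations = config$relax_iterations,
                                seed = config$seed)
      ens_cache[[key]] <- ens
    }
    outcomes$energy_ratio <- check_energy_ratio(
      pose, ens, config$energy_ratio_threshold)
  }
  if (!is.null(receptor) && any(grepl("protein|cofactor", applicable))) {
    near <- cofactors_near_ligand(receptor, pose, config$cofactor_cutoff)
    outcomes <- c(outcomes, run_intermolecular_checks(
      pose, near,
      distance_factor = config$distance_factor,
      overlap_threshold = config$overlap_threshold,
      scale_organic = config$overlap_scale_organic,
      scale_inorganic = config$overlap_scale_inorganic,
      spacing = config$overlap_grid_spacing))
  }
  rmsd <- NA_real_; within <- NA
  if (mode == "full" && length(true_mols) > 0) {
    rr <- tryCatch(symmetry_rmsd(pose, true_mols), error = function(e) NULL)
    if (!is.null(rr)) {
      rmsd <- rr$rmsd
      within <- rmsd <= config$rmsd_threshold
    }
  }
  bust_row(pose$name, pose, outcomes, applicable, rmsd, within, config)
}

topology_key <- function(pose) {
  heavy <- strip_hydrogens(pose)
  b <- heavy$bonds
  paste(paste(heavy$elements, heavy$charges, collapse = ";"),
        paste(pmin(b$i, b$j), pmax(b$i, b$j), b$order, collapse = ";"),
        sep = "|")
}

bust_row <- function(name, pose, outcomes, applicable, rmsd, within, config) {
  run <- intersect(check_names(), names(outcomes))
  relevant <- intersect(run, applicable)
  verdicts <- vapply(outcomes[relevant], function(o) isTRUE(o$passed), TRUE)
  # checks that are applicable but could not run at all count as failed
  missing <- setdiff(applicable, run)
  pose_valid <- all(verdicts) && length(missing_ok(missing, outcomes)) == 0
  list(name = name, pose = pose, outcomes = outcomes,
       applicable = applicable, rmsd = rmsd,
       rmsd_within_threshold = within, pose_valid = pose_valid)
}

# checks never attempted because the pose failed to load are genuine
# failures; consistency checks skipped for lack of a true ligand are not
missing_ok <- function(missing, outcomes) {
  if (isTRUE(outcomes$file_loads$passed)) {
    consistency <- c("molecular_formula", "bonds", "tetrahedral_chirality",
                     "double_bond_stereochemistry")
    missing <- setdiff(missing, consistency)
  }
  missing
}

#' Tabulate a bust result
#'
#' `format = "short"`: one row per pose with one logical column per check
#' (NA where inapplicable or inconclusive) plus `rmsd`,
#' `rmsd_within_threshold` and `pose_valid`. `format = "long"`: one row
#' per pose x check with the verdict and the first violating measurement.
#'
#' @param x A [bust()] result.
#' @param format `"short"` or `"long"`.
#' @return A data.frame.
#' @export
bust_table <- function(x, format = c("short", "long")) {
  format <- match.arg(format)
  if (format == "short") {
    rows <- lapply(x, function(r) {
      vals <- lapply(check_names(), function(nm) {
        o <- r$outcomes[[nm]]
        if (is.null(o) || !(nm %in% r$applicable)) NA else isTRUE(o$passed)
      })
      names(vals) <- check_names()
      cbind(data.frame(pose = r$name, stringsAsFactors = FALSE),
            as.data.frame(vals),
            data.frame(rmsd = r$rmsd,
                       rmsd_within_threshold = r$rmsd_within_threshold,
                       pose_valid = r$pose_valid))
    })
    do.call(rbind, rows)
  } else {
    rows <- list()
    for (r in x) {
      for (nm in intersect(check_names(), r$applicable)) {
        o <- r$outcomes[[nm]]
        rows[[length(rows) + 1L]] <- data.frame(
          pose = r$name, check = nm,
          passed = if (is.null(o)) NA else isTRUE(o$passed),
          detail = if (!is.null(o) && nrow(o$details) > 0) o$details$description[1] else "",
          value = if (!is.null(o) && nrow(o$details) > 0) o$details$value[1] else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
}

#' Write a bust report to CSV
#'
#' @param x A [bust()] result.
#' @param path Output CSV path.
#' @param format See [bust_table()].
#' @return Invisibly the written data.frame.
#' @export
write_report <- function(x, path, format = c("short", "long")) {
  tab <- bust_table(x, match.arg(format))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Waterfall summary of a batch
#'
#' Sequential first-failure attribution in fixed report order: each
#' failing pose is counted against the first check it fails; the final
#' count is the number of poses passing everything. The counts conserve:
#' final passes + sum of introduced failures = total poses.
#'
#' @param x A [bust()] result (rows share one test ordering).
#' @return A list of class `waterfall_summary` with `total`, `steps`
#'   (data.frame: check, failures_introduced), `final_pass`.
#' @export
waterfall <- function(x) {
  order_ <- check_names()
  counts <- stats::setNames(integer(length(order_)), order_)
  final <- 0L
  for (r in x) {
    attributed <- FALSE
    for (nm in intersect(order_, r$applicable)) {
      o <- r$outcomes[[nm]]
      failed <- if (!is.null(o)) {
        !isTRUE(o$passed)
      } else {
        # never attempted: a failure unless it was skipped for lack of a
        # reference ligand (consistency checks)
        length(missing_ok(nm, r$outcomes)) > 0
      }
      if (failed) {
        counts[nm] <- counts[nm] + 1L
        attributed <- TRUE
        break
      }
    }
    if (!attributed) final <- final + 1L
  }
  structure(list(total = length(x),
                 steps = data.frame(check = order_,
                                    failures_introduced = as.integer(counts)),
                 final_pass = final),
            class = "waterfall_summary")
}

#' @export
print.waterfall_summary <- function(x, ...) {
  cat(sprintf("<waterfall_summary> %d pose(s), %d pass all checks\n",
              x$total, x$final_pass))
  nz <- x$steps[x$steps$failures_introduced > 0, ]
  if (nrow(nz) > 0) print(nz, row.names = FALSE)
  invisible(x)
}

#' @export
print.bust_result <- function(x, ...) {
  cat(sprintf("<bust_result> %d pose(s), mode %s, %d valid\n",
              length(x), attr(x, "mode"),
              sum(vapply(x, function(r) isTRUE(r$pose_valid), TRUE))))
  invisible(x)
}
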