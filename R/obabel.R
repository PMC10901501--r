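# Thin bridge to the Open Babel command-line tools, used for standard-InChI
# generation, UFF single-point energies, force-field relaxation and
# hydrogen placement. All calls go through temporary SDF files; callers
# pass and receive mol_pose objects.

have_openbabel <- function() {
  nzchar(Sys.which("obabel")) && nzchar(Sys.which("obenergy"))
}

require_openbabel <- function() {
  if (!have_openbabel()) {
    stop("Open Babel command line tools (obabel, obenergy) are required ",
         "for this operation but were not found on PATH")
  }
}

ob_run <- function(cmd, args, stdin_file = NULL) {
  out <- suppressWarnings(system2(cmd, args,
                                  stdout = TRUE, stderr = TRUE,
                                  stdin = if (is.null(stdin_file)) "" else stdin_file))
  status <- attr(out, "status")
  list(output = out, status = if (is.null(status)) 0L else status)
}

#' Standard InChI strings for poses
#'
#' Runs Open Babel's InChI writer (standard InChI) on the given poses and
#' returns the InChI plus auxiliary-information string per molecule.
#' Stereochemistry is perceived from the 3D coordinates.
#'
#' @param mols A [mol_pose()] or list of them; aromatic bonds must already
#'   be kekulised (see the sanitisation check).
#' @return A data.frame with columns `inchi` and `auxinfo` (NA on failure).
#' @keywords internal
ob_inchi <- function(mols) {
  require_openbabel()
  if (inherits(mols, "mol_pose")) mols <- list(mols)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  write_sdf(mols, tf)
  res <- ob_run("obabel", c(tf, "-oinchi", "-xa"))
  lines <- res$output
  inchis <- grep("^InChI=", lines, value = TRUE)
  aux <- grep("^AuxInfo=", lines, value = TRUE)
  n <- length(mols)
  if (length(inchis) != n || length(aux) != n) {
    # per-molecule failure cannot be attributed reliably in batch: redo singly
    inchis <- character(n); aux <- character(n)
    for (k in seq_len(n)) {
      write_sdf(mols[[k]], tf)
      rk <- ob_run("obabel", c(tf, "-oinchi", "-xa"))
      ik <- grep("^InChI=", rk$output, value = TRUE)
      ak <- grep("^AuxInfo=", rk$output, value = TRUE)
      inchis[k] <- if (length(ik) == 1) ik else NA_character_
      aux[k] <- if (length(ak) == 1) ak else NA_character_
    }
  }
  data.frame(inchi = inchis, auxinfo = aux, stringsAsFactors = FALSE)
}

# UFF single-point energies, kcal/mol, one per molecule in the SDF.
ob_energies <- function(mols) {
  require_openbabel()
  if (inherits(mols, "mol_pose")) mols <- list(mols)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  write_sdf(mols, tf)
  res <- ob_run("obenergy", c("-ff", "UFF", tf))
  en <- grep("^TOTAL ENERGY", res$output, value = TRUE)
  kj <- as.numeric(sub("TOTAL ENERGY =\\s*([-0-9.eE+]+) kJ/mol", "\\1", en))
  if (length(kj) != length(mols)) {
    stop("UFF energy evaluation failed (", length(kj), " energies for ",
         length(mols), " molecules); unparameterised atom type?")
  }
  kj / 4.184
}

# UFF relaxation (conjugate gradients, up to `steps` iterations); returns
# the relaxed poses.
ob_minimize <- function(mols, steps = 200) {
  require_openbabel()
  if (inherits(mols, "mol_pose")) mols <- list(mols)
  tf <- tempfile(fileext = ".sdf"); to <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(tf, to)))
  write_sdf(mols, tf)
  ob_run("obabel", c(tf, "-O", to, "--minimize", "--ff", "UFF",
                     "--steps", as.character(steps), "--cg"))
  out <- load_ligands(to)
  if (length(out$poses) != length(mols)) stop("force-field relaxation failed")
  out$poses
}

# Add hydrogens with 3D coordinates (Open Babel geometric placement).
ob_add_hydrogens <- function(mol) {
  require_openbabel()
  tf <- tempfile(fileext = ".sdf"); to <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(tf, to)))
  write_sdf(mol, tf)
  ob_run("obabel", c(tf, "-O", to, "-h"))
  out <- load_ligands(to)
  if (length(out$poses) != 1) stop("hydrogen addition failed")
  out$poses[[1]]
}
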