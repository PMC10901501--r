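#' Load ligand poses from an SDF file
#'
#' Records are parsed without chemical sanitisation: valence violations and
#' kekulisation problems are accepted at parse time and judged later by the
#' sanitisation check. A record that cannot be parsed at all (corrupt counts
#' line, bond referencing a missing atom, non-finite coordinates, no heavy
#' atom) yields a failed load status for that record only -- the failure IS
#' the "file loads" test result, not an exception.
#'
#' Both V2000 and V3000 connection tables are read; `M  CHG` and `M  ISO`
#' property lines override the atom-block charge column as the format
#' prescribes.
#'
#' @param sdf_path Path to an SDF file.
#' @return A list with `poses` (list of [mol_pose()], one per successfully
#'   parsed record, `source_index` set to the record ordinal) and `status`
#'   (data.frame with `record`, `name`, `loaded`, `reason`).
#' @export
load_ligands <- function(sdf_path) {
  if (!file.exists(sdf_path)) stop("file not found: ", sdf_path)
  lines <- readLines(sdf_path, warn = FALSE)
  recs <- split_sdf_records(lines)
  poses <- list()
  status <- data.frame(record = integer(), name = character(),
                       loaded = logical(), reason = character())
  for (k in seq_along(recs)) {
    nm <- trimws(recs[[k]][1])
    res <- tryCatch(parse_sdf_record(recs[[k]], k),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      status <- rbind(status, data.frame(record = k, name = nm,
                                         loaded = FALSE, reason = res))
    } else {
      poses[[length(poses) + 1L]] <- res
      status <- rbind(status, data.frame(record = k, name = res$name,
                                         loaded = TRUE, reason = ""))
    }
  }
  list(poses = poses, status = status)
}

split_sdf_records <- function(lines) {
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) return(list())
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0) ends <- length(lines)
  starts <- c(1L, head(ends, -1) + 1L)
  recs <- list()
  for (k in seq_along(ends)) {
    body <- lines[starts[k]:ends[k]]
    body <- body[trimws(body) != "$$$$"]
    if (any(nzchar(trimws(body)))) recs[[length(recs) + 1L]] <- body
  }
  recs
}

parse_sdf_record <- function(rec, source_index) {
  if (length(rec) < 4) stop("record too short")
  counts <- rec[4]
  version <- trimws(substr(counts, 34, 39))
  if (identical(version, "V3000")) return(parse_v3000(rec, source_index))
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || na < 1) stop("bad counts line")
  if (length(rec) < 4 + na + nb) stop("truncated atom/bond block")
  atom_lines <- rec[5:(4 + na)]
  el <- trimws(substr(atom_lines, 32, 34))
  xyz <- cbind(as.numeric(substr(atom_lines, 1, 10)),
               as.numeric(substr(atom_lines, 11, 20)),
               as.numeric(substr(atom_lines, 21, 30)))
  if (!all(is.finite(xyz))) stop("non-numeric coordinates")
  # old-style charge column codes: 1..3 -> +3..+1, 5..7 -> -1..-3
  old_chg <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  old_chg[is.na(old_chg)] <- 0L
  charges <- ifelse(old_chg %in% 1:3, 4L - old_chg,
                    ifelse(old_chg %in% 5:7, 4L - old_chg, 0L))
  isotopes <- integer(na)
  bonds <- data.frame(i = integer(), j = integer(), order = integer())
  if (nb > 0) {
    bl <- rec[(5 + na):(4 + na + nb)]
    bonds <- data.frame(
      i = suppressWarnings(as.integer(substr(bl, 1, 3))),
      j = suppressWarnings(as.integer(substr(bl, 4, 6))),
      order = suppressWarnings(as.integer(substr(bl, 7, 9))))
    if (anyNA(bonds)) stop("malformed bond block")
  }
  # property block: M CHG / M ISO supersede the atom-block charge column
  prop <- rec[-seq_len(4 + na + nb)]
  chg_lines <- grep("^M  CHG", prop, value = TRUE)
  if (length(chg_lines) > 0) charges <- integer(na)
  for (ln in chg_lines) {
    v <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    cnt <- v[1]
    for (p in seq_len(cnt)) {
      idx <- v[2 * p]; q <- v[2 * p + 1]
      if (is.na(idx) || idx < 1 || idx > na) stop("M CHG references missing atom")
      charges[idx] <- q
    }
  }
  for (ln in grep("^M  ISO", prop, value = TRUE)) {
    v <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    cnt <- v[1]
    for (p in seq_len(cnt)) {
      idx <- v[2 * p]; m <- v[2 * p + 1]
      if (is.na(idx) || idx < 1 || idx > na) stop("M ISO references missing atom")
      isotopes[idx] <- m
    }
  }
  mol_pose(el, xyz, bonds, charges, isotopes,
           name = trimws(rec[1]), source_index = source_index)
}

parse_v3000 <- function(rec, source_index) {
  v30 <- sub("^M  V30 ", "", grep("^M  V30 ", rec, value = TRUE))
  ab <- which(v30 == "BEGIN ATOM"); ae <- which(v30 == "END ATOM")
  bb <- which(v30 == "BEGIN BOND"); be <- which(v30 == "END BOND")
  if (length(ab) != 1 || length(ae) != 1 || ae <= ab) stop("bad V3000 atom block")
  atoms <- v30[(ab + 1):(ae - 1)]
  tok <- strsplit(trimws(atoms), "\\s+")
  el <- vapply(tok, `[[`, "", 2)
  xyz <- t(vapply(tok, function(t) as.numeric(t[3:5]), numeric(3)))
  if (!all(is.finite(xyz))) stop("non-numeric V3000 coordinates")
  na <- length(el)
  charges <- integer(na); isotopes <- integer(na)
  for (k in seq_along(tok)) {
    for (f in tok[[k]][-(1:6)]) {
      if (grepl("^CHG=", f)) charges[k] <- as.integer(sub("CHG=", "", f))
      if (grepl("^MASS=", f)) isotopes[k] <- as.integer(sub("MASS=", "", f))
    }
  }
  bonds <- data.frame(i = integer(), j = integer(), order = integer())
  if (length(bb) == 1 && length(be) == 1 && be > bb + 1) {
    btok <- strsplit(trimws(v30[(bb + 1):(be - 1)]), "\\s+")
    bonds <- data.frame(
      i = vapply(btok, function(t) as.integer(t[3]), 1L),
      j = vapply(btok, function(t) as.integer(t[4]), 1L),
      order = vapply(btok, function(t) as.integer(t[2]), 1L))
    if (anyNA(bonds)) stop("malformed V3000 bond block")
  }
  mol_pose(el, xyz, bonds, charges, isotopes,
           name = trimws(rec[1]), source_index = source_index)
}

#' Write molecule poses to SDF (V2000) text
#'
#' Formal charges and isotopes are written as `M  CHG`/`M  ISO` property
#' lines so they survive a round trip through [load_ligands()].
#'
#' @param mols A [mol_pose()] or list of them.
#' @param path Optional output file; when `NULL` the SDF text is returned.
#' @return Invisibly (or visibly when `path` is `NULL`) the SDF text as a
#'   character vector of lines.
#' @export
write_sdf <- function(mols, path = NULL) {
  if (inherits(mols, "mol_pose")) mols <- list(mols)
  out <- character()
  for (mol in mols) {
    n <- n_atoms(mol); nb <- nrow(mol$bonds)
    lines <- c(mol$name, " poseval", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
    for (k in seq_len(n)) {
      lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                                mol$xyz[k, 1], mol$xyz[k, 2], mol$xyz[k, 3],
                                mol$elements[k]))
    }
    for (k in seq_len(nb)) {
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                mol$bonds$i[k], mol$bonds$j[k], mol$bonds$order[k]))
    }
    for (k in which(mol$charges != 0)) {
      lines <- c(lines, sprintf("M  CHG  1 %3d %3d", k, mol$charges[k]))
    }
    for (k in which(mol$isotopes != 0)) {
      lines <- c(lines, sprintf("M  ISO  1 %3d %3d", k, mol$isotopes[k]))
    }
    lines <- c(lines, "M  END", "$$$$")
    out <- c(out, lines)
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
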