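# Chemical validity and consistency checks: sanitisation (valence /
# aromaticity / Lewis-structure consistency) and standard-InChI layer
# comparison between predicted and reference ligands.

default_valence <- function(el) {
  switch(el,
         H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
         Si = 4L, P = 3L, S = 2L, Cl = 1L, Se = 2L, Br = 1L, I = 1L,
         NA_integer_)
}

max_allowed_valence <- function(el, charge) {
  base <- switch(el,
                 H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, Si = 4L,
                 P = 5L, S = 6L, Cl = 1L, Se = 6L, Br = 1L, I = 3L,
                 NA_integer_)
  if (is.na(base)) return(NA_integer_)  # metals etc.: no valence test
  if (el %in% c("N", "O", "P", "S", "Se", "F", "Cl", "Br", "I")) {
    base + charge
  } else {
    base - abs(charge)
  }
}

#' Sanitisation check
#'
#' Verifies that the molecule admits an octet-complete Lewis structure:
#' aromatic bonds must lie in rings and kekulise to an alternating
#' single/double pattern, and no atom may exceed its maximum allowed
#' valence for its element and formal charge. Internal errors never
#' propagate; they are reported as a failed outcome with a reason.
#'
#' @param mol A [mol_pose()].
#' @return A [check_outcome()] named `"sanitisation"`.
#' @export
check_sanitises <- function(mol) {
  res <- tryCatch(sanitise_mol(mol), error = function(e) conditionMessage(e))
  if (is.character(res)) {
    return(check_outcome("sanitisation", FALSE, detail_row(res, NA_real_)))
  }
  check_outcome("sanitisation", TRUE)
}

# Kekulises and valence-checks; returns the kekulised molecule or errors
# with a reason.
sanitise_mol <- function(mol) {
  heavy <- strip_hydrogens(mol)
  arom <- which(heavy$bonds$order == 4L)
  if (length(arom) > 0) {
    rings <- smallest_rings(heavy)
    in_ring <- matrix(FALSE, n_atoms(heavy), n_atoms(heavy))
    for (ring in rings) {
      nr <- length(ring)
      pr <- cbind(ring, ring[c(2:nr, 1)])
      in_ring[pr] <- TRUE; in_ring[pr[, 2:1]] <- TRUE
    }
    bad <- !in_ring[cbind(heavy$bonds$i[arom], heavy$bonds$j[arom])]
    if (any(bad)) stop("aromatic bond outside any ring")
  }
  kek <- kekulise(heavy)
  if (is.null(kek)) stop("kekulisation failed: no alternating bond assignment")
  bo <- bond_order_matrix(kek)
  val <- rowSums(bo) + kek$h_count
  for (a in seq_len(n_atoms(kek))) {
    mx <- max_allowed_valence(kek$elements[a], kek$charges[a])
    if (!is.na(mx) && val[a] > mx) {
      stop(sprintf("valence violation: %s%+d at atom %d has valence %d (max %d)",
                   kek$elements[a], kek$charges[a], a, val[a], mx))
    }
  }
  kek
}

# Neutralise formal charges by adding or removing hydrogens where possible:
# a cation loses a proton if it carries one (explicit or implicit), an
# anion gains one if it has an open valence. Quaternary ammonium and
# similar centres are left charged. Operates on the full molecule
# (hydrogens intact); implicit hydrogen bookkeeping absorbs the change when
# no explicit hydrogen is present.
neutralise_charges <- function(mol) {
  drop_h <- integer()
  bo <- bond_order_matrix(mol)
  order_sum <- rowSums(bo)
  for (a in which(mol$charges != 0)) {
    q <- mol$charges[a]; el <- mol$elements[a]
    dv <- default_valence(el)
    if (is.na(dv)) next  # metal ions stay charged
    if (q > 0) {
      h_nb <- which(mol$elements == "H" & bo[a, ] > 0)
      n_expl <- length(h_nb)
      n_impl <- max(0, dv + q - order_sum[a])
      if (n_expl + n_impl >= q) {
        take <- head(h_nb, min(q, n_expl))
        drop_h <- c(drop_h, take)
        mol$charges[a] <- 0L
      }
    } else {
      open <- dv - q - order_sum[a]  # valence slots at neutral minus current
      if (open >= 0) mol$charges[a] <- 0L
    }
  }
  if (length(drop_h) > 0) {
    keep <- setdiff(seq_len(n_atoms(mol)), drop_h)
    hmap <- match(seq_len(n_atoms(mol)), keep)
    b <- mol$bonds
    b <- b[!is.na(hmap[b$i]) & !is.na(hmap[b$j]), , drop = FALSE]
    b$i <- hmap[b$i]; b$j <- hmap[b$j]
    mol <- mol_pose(mol$elements[keep], mol$xyz[keep, , drop = FALSE], b,
                    mol$charges[keep], mol$isotopes[keep], mol$name,
                    mol$source_index)
  }
  mol
}

# Primary ketimines R2C=NH: the E/Z label depends only on the ambiguous
# hydrogen location, so their double-bond stereo is dropped before layer
# comparison. Returns heavy-atom index pairs (C, N).
find_primary_ketimines <- function(mol) {
  heavy <- strip_hydrogens(mol)
  bo <- bond_order_matrix(heavy)
  deg <- rowSums(bo > 0)
  out <- list()
  b <- heavy$bonds
  for (k in which(b$order == 2L)) {
    for (swap in c(FALSE, TRUE)) {
      ci <- if (swap) b$j[k] else b$i[k]
      ni <- if (swap) b$i[k] else b$j[k]
      # the N of a neutral =NH carries exactly one hydrogen, whether it
      # is explicit (h_count 1) or implicit (h_count 0)
      if (heavy$elements[ci] == "C" && heavy$elements[ni] == "N" &&
          heavy$charges[ni] == 0L &&
          deg[ni] == 1 && heavy$h_count[ni] <= 1 && deg[ci] == 3) {
        out[[length(out) + 1L]] <- c(ci, ni)
      }
    }
  }
  out
}

#' Standardise a molecule and split its standard InChI into layers
#'
#' Clears isotope labels, neutralises formal charges by adding or removing
#' hydrogens where possible, removes the double-bond stereo label of
#' primary ketimines, then generates the standard InChI (stereochemistry
#' perceived from the 3D coordinates) and splits it into layers.
#'
#' @param mol A [mol_pose()].
#' @return A list of class `inchi_layers` with character fields `formula`,
#'   `c` (connections), `h` (hydrogens), `q` (charge), `p` (protons),
#'   `b` (double-bond stereo), `t` (tetrahedral), `m`, `s`; missing layers
#'   are empty strings. `NULL` on InChI generation failure.
#' @export
standardise <- function(mol) {
  mol$isotopes[] <- 0L
  mol <- neutralise_charges(mol)
  kek <- tryCatch(sanitise_mol(mol), error = function(e) NULL)
  towrite <- if (is.null(kek)) mol else {
    # keep hydrogens of the original but kekulised orders on heavy bonds
    m2 <- mol
    heavy_idx <- which(is_heavy(mol))
    hb <- m2$bonds$i %in% heavy_idx & m2$bonds$j %in% heavy_idx
    key_full <- paste(pmin(match(m2$bonds$i, heavy_idx), match(m2$bonds$j, heavy_idx)),
                      pmax(match(m2$bonds$i, heavy_idx), match(m2$bonds$j, heavy_idx)))
    key_kek <- paste(pmin(kek$bonds$i, kek$bonds$j), pmax(kek$bonds$i, kek$bonds$j))
    m2$bonds$order[hb] <- kek$bonds$order[match(key_full[hb], key_kek)]
    m2
  }
  ket <- find_primary_ketimines(towrite)
  res <- ob_inchi(towrite)
  if (is.na(res$inchi[1])) return(NULL)
  layers <- split_inchi_layers(res$inchi[1])
  if (length(ket) > 0 && !is.na(res$auxinfo[1])) {
    layers <- drop_b_entries(layers, res$auxinfo[1], ket, towrite)
  }
  layers
}

split_inchi_layers <- function(inchi) {
  body <- sub("^InChI=1S?/", "", inchi)
  parts <- strsplit(body, "/", fixed = TRUE)[[1]]
  out <- list(formula = parts[1], c = "", h = "", q = "", p = "",
              b = "", t = "", m = "", s = "", i = "")
  for (p in parts[-1]) {
    tag <- substr(p, 1, 1)
    if (tag %in% names(out)) out[[tag]] <- substr(p, 2, nchar(p))
  }
  class(out) <- "inchi_layers"
  out
}

# Remove from the /b layer the entries that belong to the given heavy-atom
# pairs, using the AuxInfo canonical-numbering map (/N: layer, canonical
# position -> original atom number).
drop_b_entries <- function(layers, auxinfo, pairs, mol) {
  if (!nzchar(layers$b)) return(layers)
  nmap <- regmatches(auxinfo, regexpr("/N:[0-9,;]+", auxinfo))
  if (length(nmap) == 0) return(layers)
  nums <- sub("^/N:", "", nmap)
  if (grepl(";", nums)) return(layers)  # multi-component: leave untouched
  orig <- as.integer(strsplit(nums, ",")[[1]])  # orig[k] = input index of canonical k
  heavy_input <- which(is_heavy(mol))  # InChI input numbering includes H as written
  entries <- strsplit(layers$b, ",")[[1]]
  keep <- rep(TRUE, length(entries))
  for (pr in pairs) {
    # pr are heavy-atom indices; convert to input (full-molecule) indices
    ci <- heavy_input[pr[1]]; ni <- heavy_input[pr[2]]
    c_can <- which(orig == ci); n_can <- which(orig == ni)
    if (length(c_can) != 1 || length(n_can) != 1) next
    tag1 <- sprintf("%d-%d", max(c_can, n_can), min(c_can, n_can))
    keep[grepl(paste0("^", tag1, "[+?-]"), entries)] <- FALSE
  }
  layers$b <- paste(entries[keep], collapse = ",")
  layers
}

#' Compare predicted and reference ligands for chemical consistency
#'
#' Standardises both molecules and compares standard-InChI layers:
#' the formula check compares the formula plus net-charge (/q) and proton
#' (/p) layers; the bonds check compares connections (/c) plus hydrogen
#' (/h) layers; tetrahedral chirality compares /t with its /m and /s
#' sub-layers; double-bond stereochemistry compares /b. Stereo specified in
#' exactly one of the two molecules fails the respective check.
#'
#' @param pred,true_mol [mol_pose()] objects sharing an intended identity.
#' @return Named list of four [check_outcome()]s: `molecular_formula`,
#'   `bonds`, `tetrahedral_chirality`, `double_bond_stereochemistry`.
#' @export
compare_consistency <- function(pred, true_mol) {
  lp <- tryCatch(standardise(pred), error = function(e) NULL)
  lt <- tryCatch(standardise(true_mol), error = function(e) NULL)
  if (is.null(lp) || is.null(lt)) {
    fail <- function(nm) check_outcome(nm, FALSE,
      detail_row("standardisation failed (InChI unavailable)", NA_real_))
    return(list(molecular_formula = fail("molecular_formula"),
                bonds = fail("bonds"),
                tetrahedral_chirality = fail("tetrahedral_chirality"),
                double_bond_stereochemistry = fail("double_bond_stereochemistry")))
  }
  cmp <- function(nm, fields) {
    same <- vapply(fields, function(f) identical(lp[[f]], lt[[f]]), TRUE)
    if (all(same)) return(check_outcome(nm, TRUE))
    bad <- fields[!same]
    det <- do.call(rbind, lapply(bad, function(f)
      detail_row(sprintf("layer /%s differs: '%s' vs '%s'", f, lp[[f]], lt[[f]]),
                 NA_real_)))
    check_outcome(nm, FALSE, det)
  }
  list(molecular_formula = cmp("molecular_formula", c("formula", "q", "p")),
       bonds = cmp("bonds", c("c", "h")),
       tetrahedral_chirality = cmp("tetrahedral_chirality", c("t", "m", "s")),
       double_bond_stereochemistry = cmp("double_bond_stereochemistry", "b"))
}
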