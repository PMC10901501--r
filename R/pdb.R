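# Receptor structure input: parse a PDB file, classify HETATM residues
# into organic and inorganic cofactor groups, drop waters, and extract
# chain sequences.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL",
                 "MSE", "SEC", "PYL")  # common substitutions kept as protein
WATER_RES <- c("HOH", "WAT", "DOD")

#' Load a receptor structure from a PDB file
#'
#' ATOM records with standard amino-acid residue names become protein
#' atoms. Non-water HETATM residues are split into organic (containing at
#' least one carbon) and inorganic (no carbon: metal ions, clusters)
#' cofactor groups, one group per residue. Waters (HOH/WAT/DOD) are
#' removed. For alternate locations the highest-occupancy conformer is
#' kept (ties: first encountered). Chain sequences are extracted from the
#' protein residues in order.
#'
#' @param pdb_path Path to a PDB file.
#' @return A list of class `receptor_structure` with `protein_atoms`
#'   (data.frame: element, x, y, z, resid, chain, resno),
#'   `organic_cofactors` and `inorganic_cofactors` (lists of data.frames:
#'   element, x, y, z, resid), `chains` (named character vector of
#'   one-letter sequences) and `n_waters_removed`.
#' @export
load_receptor <- function(pdb_path) {
  if (!file.exists(pdb_path)) stop("file not found: ", pdb_path)
  pdb <- bio3d::read.pdb(pdb_path, verbose = FALSE)
  at <- pdb$atom
  # altloc: keep highest occupancy per (chain, resno, atom name), tie first
  alt <- ifelse(is.na(at$alt), "", at$alt)
  if (any(nzchar(alt) & alt != " ")) {
    key <- paste(at$chain, at$resno, at$resid, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(key, -occ, seq_len(nrow(at)))
    at <- at[ord, ][!duplicated(key[ord]), ]
    at <- at[order(as.integer(rownames(at))), ]
  }
  el <- trimws(at$elesy)
  noel <- is.na(el) | !nzchar(el)
  el[noel] <- vapply(at$elety[noel], element_from_atom_name, "")
  el <- normalise_element_case(el)
  at$element <- el
  is_water <- at$resid %in% WATER_RES
  n_waters <- length(unique(paste(at$chain[is_water], at$resno[is_water])))
  at <- at[!is_water, ]
  is_protein <- at$type == "ATOM" & at$resid %in% STANDARD_AA
  prot <- at[is_protein, c("element", "x", "y", "z", "resid", "chain", "resno")]
  if (nrow(prot) == 0) stop("no protein atoms in ", pdb_path)
  het <- at[!is_protein, ]
  organic <- list(); inorganic <- list()
  if (nrow(het) > 0) {
    unknown <- het$type == "ATOM"
    if (any(unknown)) {
      warning("unknown residue name(s) treated as cofactor: ",
              paste(unique(het$resid[unknown]), collapse = ", "))
    }
    grp <- split(het, paste(het$chain, het$resno, het$resid))
    for (g in grp) {
      d <- g[, c("element", "x", "y", "z", "resid")]
      if (any(d$element == "C")) organic[[length(organic) + 1L]] <- d
      else inorganic[[length(inorganic) + 1L]] <- d
    }
  }
  chains <- vapply(split(prot, prot$chain), function(p) {
    res <- p[!duplicated(paste(p$resno, p$resid)), ]
    res <- res[order(res$resno), ]
    paste(bio3d::aa321(res$resid), collapse = "")
  }, "")
  structure(list(protein_atoms = prot, organic_cofactors = organic,
                 inorganic_cofactors = inorganic, chains = chains,
                 n_waters_removed = n_waters),
            class = "receptor_structure")
}

#' @export
print.receptor_structure <- function(x, ...) {
  cat(sprintf("<receptor_structure> %d protein atoms, %d chain(s), %d organic / %d inorganic cofactor group(s)\n",
              nrow(x$protein_atoms), length(x$chains),
              length(x$organic_cofactors), length(x$inorganic_cofactors)))
  invisible(x)
}

element_from_atom_name <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  two <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "CA", "CU", "NI", "CO", "SE")
  if (toupper(nm) %in% two && nchar(trimws(name)) <= 2) return(toupper(nm))
  substr(nm, 1, 1)
}

normalise_element_case <- function(el) {
  el <- toupper(el)
  paste0(substr(el, 1, 1), tolower(substr(el, 2, nchar(el))))
}

#' Cofactor groups near a ligand
#'
#' Restricts the receptor's cofactor groups to those with at least one
#' heavy atom within `cutoff` of at least one ligand heavy atom.
#'
#' @param receptor A [load_receptor()] result.
#' @param ligand A [mol_pose()].
#' @param cutoff Distance cutoff in Angstrom (default 4.0).
#' @return The receptor with `organic_cofactors` and `inorganic_cofactors`
#'   reduced to the nearby subsets.
#' @export
cofactors_near_ligand <- function(receptor, ligand, cutoff = 4.0) {
  lig <- as_atom_set(ligand)
  near <- function(groups) {
    keep <- vapply(groups, function(g) {
      h <- g[g$element != "H", , drop = FALSE]
      if (nrow(h) == 0) return(FALSE)
      xyz <- as.matrix(h[, c("x", "y", "z")])
      d2 <- outer(rowSums(xyz^2), rowSums(lig$xyz^2), "+") -
        2 * xyz %*% t(lig$xyz)
      min(d2) <= cutoff^2
    }, TRUE)
    groups[keep]
  }
  receptor$organic_cofactors <- near(receptor$organic_cofactors)
  receptor$inorganic_cofactors <- near(receptor$inorganic_cofactors)
  receptor
}
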