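# Symmetry-aware heavy-atom RMSD: the minimum root-mean-square coordinate
# deviation over all chemically equivalent atom mappings (graph
# isomorphisms with element and bond-order matching) between the predicted
# pose and each reference copy. No re-superposition is performed: in
# re-docking evaluation the prediction and the crystal ligand share the
# receptor frame.

mol_colored_graph <- function(mol) {
  heavy <- strip_hydrogens(mol)
  # perceived-aromatic ring bonds are labelled uniformly so kekule
  # alternation does not split chemically equivalent mappings
  rings <- smallest_rings(heavy)
  arom <- perceive_aromatic_rings(heavy, rings)
  b <- heavy$bonds
  bkey <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
  for (r in arom) {
    ring <- rings[[r]]
    nr <- length(ring)
    rkey <- paste(pmin(ring, ring[c(2:nr, 1)]), pmax(ring, ring[c(2:nr, 1)]))
    b$order[bkey %in% rkey] <- 4L
  }
  vcol <- as.integer(factor(paste(heavy$elements, heavy$charges),
                            levels = sort(unique(c(paste(heavy$elements, heavy$charges))))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = b$i, to = b$j), directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(heavy))))
  list(graph = g, vcol = vcol, ecol = b$order, xyz = heavy$xyz,
       labels = paste(heavy$elements, heavy$charges), edges = b)
}

#' Symmetry-aware RMSD between a predicted pose and reference copies
#'
#' Enumerates all graph isomorphisms of the heavy-atom graphs (element,
#' formal charge and bond-order matching; aromatic rings matched as
#' aromatic regardless of kekule form) and returns the minimum RMSD over
#' mappings and reference copies, computed on raw coordinates without
#' refitting.
#'
#' @param pred A [mol_pose()].
#' @param true_mols A [mol_pose()] or list of them (reference copies with
#'   the same heavy-atom molecular graph).
#' @param max_mappings Cap on enumerated mappings per reference copy
#'   (default 10000); beyond the cap the best mapping found so far is
#'   reported and flagged.
#' @return A list of class `rmsd_result`: `rmsd` (Angstrom),
#'   `matched_true_index`, `n_mappings_considered`, `capped` (logical).
#' @export
symmetry_rmsd <- function(pred, true_mols, max_mappings = 10000) {
  if (inherits(true_mols, "mol_pose")) true_mols <- list(true_mols)
  if (length(true_mols) == 0) stop("no reference molecules")
  gp <- mol_colored_graph(pred)
  best <- Inf; best_idx <- NA_integer_; n_considered <- 0L; capped <- FALSE
  for (ti in seq_along(true_mols)) {
    gt <- mol_colored_graph(true_mols[[ti]])
    if (length(gt$vcol) != length(gp$vcol) ||
        !identical(sort(gt$labels), sort(gp$labels))) {
      stop("heavy-atom graphs do not match (run the consistency checks)")
    }
    # vertex colors must come from one shared level set
    levs <- sort(unique(c(gp$labels, gt$labels)))
    vc1 <- as.integer(factor(gp$labels, levels = levs))
    vc2 <- as.integer(factor(gt$labels, levels = levs))
    maps <- igraph::isomorphisms(gp$graph, gt$graph, method = "vf2",
                                 vertex.color1 = vc1, vertex.color2 = vc2,
                                 edge.color1 = gp$ecol, edge.color2 = gt$ecol)
    if (length(maps) == 0) stop("heavy-atom graphs do not match (no isomorphism)")
    if (length(maps) > max_mappings) {
      maps <- maps[seq_len(max_mappings)]
      capped <- TRUE
    }
    n_considered <- n_considered + length(maps)
    for (m in maps) {
      # igraph returns, per mapping, the sequence p with: vertex i of the
      # second graph corresponds to vertex p[i] of the first
      perm <- as.integer(igraph::as_ids(m))
      delta <- gp$xyz[perm, , drop = FALSE] - gt$xyz
      r <- sqrt(mean(rowSums(delta^2)))
      if (r < best) { best <- r; best_idx <- ti }
    }
  }
  structure(list(rmsd = best, matched_true_index = best_idx,
                 n_mappings_considered = n_considered, capped = capped),
            class = "rmsd_result")
}

#' @export
print.rmsd_result <- function(x, ...) {
  cat(sprintf("<rmsd_result> %.4f Angstrom (reference copy %d, %d mapping(s)%s)\n",
              x$rmsd, x$matched_true_index, x$n_mappings_considered,
              if (x$capped) ", capped" else ""))
  invisible(x)
}

#' Coverage: share of poses within an RMSD threshold
#'
#' The boundary counts as within (`<=`).
#'
#' @param rmsds Numeric vector of RMSD values (Angstrom).
#' @param threshold Threshold in Angstrom (default 2.0).
#' @return Fraction in `[0, 1]`.
#' @export
coverage <- function(rmsds, threshold = 2.0) {
  if (length(rmsds) == 0) stop("coverage of an empty set is undefined")
  mean(rmsds <= threshold)
}
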