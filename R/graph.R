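# Molecular graph utilities shared by the consistency and geometry checks:
# ring perception, aromaticity, kekulisation, hybridisation. These operate
# on heavy-atom poses (see strip_hydrogens); hydrogen counts enter through
# the h_count field.

adjacency_list <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

bond_order_matrix <- function(mol) {
  n <- n_atoms(mol)
  m <- matrix(0L, n, n)
  b <- mol$bonds
  m[cbind(b$i, b$j)] <- b$order
  m[cbind(b$j, b$i)] <- b$order
  m
}

# Smallest rings: for every bond, the shortest cycle through it (Figueras
# style); duplicates removed. Adequate for drug-like ring systems.
smallest_rings <- function(mol, max_size = 8) {
  b <- mol$bonds
  if (nrow(b) == 0) return(list())
  g <- igraph::graph_from_data_frame(
    data.frame(from = b$i, to = b$j), directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(mol))))
  rings <- list()
  seen <- character()
  for (k in seq_len(nrow(b))) {
    eid <- igraph::get_edge_ids(g, c(b$i[k], b$j[k]))
    g2 <- igraph::delete_edges(g, eid)
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = b$i[k], to = b$j[k]))
    vp <- sp$vpath[[1]]
    if (length(vp) == 0 || length(vp) > max_size) next
    ring <- as.integer(igraph::as_ids(vp))
    key <- paste(sort(ring), collapse = "-")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- ring  # in cycle order
    }
  }
  rings
}

# Returns indices of rings (from smallest_rings) perceived as aromatic.
# A ring is aromatic if its bonds are marked aromatic in the input, or if
# it is a 5/6-ring in which every atom is sp2-capable (has a double or
# aromatic bond, or is N/O/S able to donate a lone pair) and the ring
# passes a kekulisation attempt. This is deliberately simpler than full
# Hueckel perception; see the methods vignette.
perceive_aromatic_rings <- function(mol, rings = smallest_rings(mol)) {
  if (length(rings) == 0) return(integer())
  bo <- bond_order_matrix(mol)
  hc <- if (!is.null(mol$h_count)) mol$h_count else explicit_h_counts(mol)
  deg <- lengths(adjacency_list(mol))
  arom <- logical(length(rings))
  for (r in seq_along(rings)) {
    ring <- rings[[r]]
    nr <- length(ring)
    if (!(nr %in% c(5, 6))) next
    ring_pairs <- cbind(ring, ring[c(2:nr, 1)])
    orders <- bo[ring_pairs]
    if (all(orders == 4L)) { arom[r] <- TRUE; next }
    if (any(orders == 4L)) { arom[r] <- TRUE; next }  # partially marked: trust marks
    # kekule form: sp2-capability test
    ok <- TRUE
    for (a in ring) {
      el <- mol$elements[a]
      has_pi <- any(bo[a, ] %in% c(2L, 4L))
      lone_pair_donor <- el %in% c("N", "O", "S") && !has_pi &&
        (el != "N" || (deg[a] + hc[a]) >= 3)
      if (!(has_pi || lone_pair_donor)) { ok <- FALSE; break }
    }
    if (!ok) next
    # alternation check: double bonds in the ring must tile the pi atoms
    pi_atoms <- ring[vapply(ring, function(a) any(bo[a, ] == 2L), TRUE)]
    n_db_in_ring <- sum(bo[ring_pairs] == 2L)
    arom[r] <- length(pi_atoms) == 2 * n_db_in_ring && n_db_in_ring >= 2
  }
  which(arom)
}

# Kekulise aromatic (order 4) bonds into alternating single/double via
# backtracking matching. Atoms that need a pi double bond are determined by
# element/charge/connectivity; lone-pair donors (pyrrole N, furan O) are
# left unmatched. Returns the molecule with orders rewritten, or NULL if no
# valid assignment exists (a kekulisation failure, judged by the
# sanitisation check).
kekulise <- function(mol) {
  b <- mol$bonds
  arom_idx <- which(b$order == 4L)
  if (length(arom_idx) == 0) return(mol)
  hc <- if (!is.null(mol$h_count)) mol$h_count else explicit_h_counts(mol)
  deg <- lengths(adjacency_list(mol))
  bo <- bond_order_matrix(mol)
  atoms <- sort(unique(c(b$i[arom_idx], b$j[arom_idx])))
  needs <- logical(n_atoms(mol))
  for (a in atoms) {
    el <- mol$elements[a]; q <- mol$charges[a]
    conn <- deg[a] + hc[a]
    has_exo_pi <- any(bo[a, ] == 2L)  # e.g. quinone carbonyl carbon
    needs[a] <- if (has_exo_pi) FALSE
    else if (el == "C") q == 0 || q == 1  # carbanion/carbocation edge: match C0/C+
    else if (el == "N") (q == 0 && conn <= 2) || (q == 1 && conn == 3)
    else if (el == "P") (q == 0 && conn <= 2)
    else if (el %in% c("O", "S", "Se")) q == 1
    else FALSE
  }
  need_atoms <- atoms[needs[atoms]]
  # backtracking perfect matching on need_atoms over aromatic bonds
  pairs <- cbind(b$i[arom_idx], b$j[arom_idx])
  matched <- integer(0)
  assign_db <- function(remaining, used_bonds) {
    if (length(remaining) == 0) return(used_bonds)
    a <- remaining[1]
    cand <- which((pairs[, 1] == a & pairs[, 2] %in% remaining) |
                  (pairs[, 2] == a & pairs[, 1] %in% remaining))
    for (kb in cand) {
      other <- if (pairs[kb, 1] == a) pairs[kb, 2] else pairs[kb, 1]
      res <- assign_db(setdiff(remaining, c(a, other)), c(used_bonds, kb))
      if (!is.null(res)) return(res)
    }
    NULL
  }
  sol <- assign_db(need_atoms, integer(0))
  if (is.null(sol) && length(need_atoms) > 0) return(NULL)
  b$order[arom_idx] <- 1L
  b$order[arom_idx[sol]] <- 2L
  mol$bonds <- b
  mol
}

# Hybridisation guess per heavy atom: "sp", "sp2", "sp3", from bond orders
# (aromatic counts as sp2).
hybridisation <- function(mol) {
  bo <- bond_order_matrix(mol)
  n <- n_atoms(mol)
  vapply(seq_len(n), function(a) {
    orders <- bo[a, bo[a, ] > 0]
    if (any(orders == 3L) || sum(orders == 2L) >= 2) "sp"
    else if (any(orders %in% c(2L, 4L))) "sp2"
    else "sp3"
  }, "")
}
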