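# Independent oracles used by both the unit tests and the acceptance
# tests. Each is deliberately implemented without the package's own code
# path for the quantity it checks.

# --- alignment: quadratic affine-gap local DP (Gotoh), scores only;
# first gapped position scores gap_open, each further one gap_extend
sw_oracle <- function(q, t, mat, gap_open = -11, gap_extend = -1) {
  qq <- strsplit(q, "")[[1]]; tt <- strsplit(t, "")[[1]]
  n <- length(qq); m <- length(tt)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[qq[i - 1], tt[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + gap_open, X[i - 1, j] + gap_extend)
      Y[i, j] <- max(M[i, j - 1] + gap_open, Y[i, j - 1] + gap_extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

blosum62_matrix <- function() {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# --- RMSD: enumerate ALL element/charge/bond-order-preserving mappings by
# backtracking over adjacency (no igraph)
brute_isomorphism_rmsd <- function(pred, true_mol) {
  a <- strip_hydrogens(pred); b <- strip_hydrogens(true_mol)
  n <- length(a$elements)
  boa <- poseval:::bond_order_matrix(a)
  bob <- poseval:::bond_order_matrix(b)
  norm_orders <- function(m, mol) {
    rings <- poseval:::smallest_rings(mol)
    arom <- poseval:::perceive_aromatic_rings(mol, rings)
    for (r in arom) {
      ring <- rings[[r]]
      nr <- length(ring)
      prs <- cbind(ring, ring[c(2:nr, 1)])
      m[prs] <- 4L; m[prs[, 2:1]] <- 4L
    }
    m
  }
  boa <- norm_orders(boa, a); bob <- norm_orders(bob, b)
  best <- Inf
  assign <- integer(n); used <- logical(n)
  recurse <- function(i) {
    if (i > n) {
      d <- a$xyz - b$xyz[assign, , drop = FALSE]
      best <<- min(best, sqrt(mean(rowSums(d^2))))
      return()
    }
    for (cand in which(!used)) {
      if (a$elements[i] != b$elements[cand]) next
      if (a$charges[i] != b$charges[cand]) next
      ok <- TRUE
      for (j in seq_len(i - 1)) {
        if (boa[i, j] != bob[cand, assign[j]]) { ok <- FALSE; break }
      }
      if (!ok) next
      assign[i] <<- cand; used[cand] <<- TRUE
      recurse(i + 1)
      used[cand] <<- FALSE
    }
  }
  recurse(1)
  best
}

# --- geometry: classify every heavy-atom pair from scratch and scan it
# against the same bounds matrix; returns the three verdicts
geometry_scan_oracle <- function(mol, b, tol_bond = 0.25, tol_clash = 0.30) {
  heavy <- strip_hydrogens(mol)
  n <- length(heavy$elements)
  d <- as.matrix(dist(heavy$xyz))
  bonded <- matrix(FALSE, n, n)
  bonded[cbind(heavy$bonds$i, heavy$bonds$j)] <- TRUE
  bonded <- bonded | t(bonded)
  onethree <- matrix(FALSE, n, n)
  for (j in seq_len(n)) {
    nb <- which(bonded[j, ])
    for (a in nb) for (c_ in nb) if (a < c_ && !bonded[a, c_])
      onethree[a, c_] <- onethree[c_, a] <- TRUE
  }
  bl <- TRUE; ba <- TRUE; cl <- TRUE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (bonded[i, j]) {
      if (d[i, j] < (1 - tol_bond) * b$lower[i, j] ||
          d[i, j] > (1 + tol_bond) * b$upper[i, j]) bl <- FALSE
    } else if (onethree[i, j]) {
      if (d[i, j] < (1 - tol_bond) * b$lower[i, j] ||
          d[i, j] > (1 + tol_bond) * b$upper[i, j]) ba <- FALSE
    } else {
      if (d[i, j] < (1 - tol_clash) * b$lower[i, j]) cl <- FALSE
    }
  }
  c(bl, ba, cl)
}

# analytic overlap share of two equal spheres of radius r at distance x*r
lens_share <- function(x) (1 / 16) * (x - 2)^2 * (x + 4)
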