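# Synthetic fixture generator: a small library of drug-like toy molecules
# with deterministic embedded conformers, targeted single-defect
# distortions (each designed to trip exactly one validity check), and a
# toy receptor-ligand complex so every check has positive and negative
# tests without any external structure.

#' Names of the built-in fixture templates
#' @return Character vector of template names.
#' @export
fixture_templates <- function() names(template_library())

template_library <- function() {
  mk <- function(elements, i, j, order, charges = integer(length(elements)),
                 chiral = NULL, dbstereo = NULL) {
    list(elements = elements,
         bonds = data.frame(i = i, j = j, order = as.integer(order)),
         charges = as.integer(charges), chiral = chiral, dbstereo = dbstereo)
  }
  ring6 <- function() list(i = 1:6, j = c(2:6, 1), order = rep(4L, 6))
  r <- ring6()
  list(
    benzene = mk(rep("C", 6), r$i, r$j, r$order),
    toluene = mk(c(rep("C", 6), "C"), c(r$i, 1), c(r$j, 7), c(r$order, 1L)),
    phenol = mk(c(rep("C", 6), "O"), c(r$i, 1), c(r$j, 7), c(r$order, 1L)),
    aniline = mk(c(rep("C", 6), "N"), c(r$i, 1), c(r$j, 7), c(r$order, 1L)),
    pyridine = mk(c("N", rep("C", 5)), r$i, r$j, r$order),
    furan = mk(c("O", rep("C", 4)), 1:5, c(2:5, 1), c(1L, 4L, 4L, 4L, 1L)),
    hexane = mk(rep("C", 6), 1:5, 2:6, rep(1L, 5)),
    cyclohexane = mk(rep("C", 6), 1:6, c(2:6, 1), rep(1L, 6)),
    isobutane = mk(rep("C", 4), c(1, 1, 1), c(2, 3, 4), rep(1L, 3)),
    # (R)-butan-2-ol: chiral centre at C2 with neighbours C1, C3, O5
    butan2ol = mk(c("C", "C", "C", "C", "O"), c(1, 2, 3, 2), c(2, 3, 4, 5),
                  rep(1L, 4), chiral = list(center = 2L, nbrs = c(1L, 3L, 5L),
                                            sign = 1)),
    cis_butene = mk(rep("C", 4), 1:3, 2:4, c(1L, 2L, 1L),
                    dbstereo = list(pair = c(1L, 4L), distance = 2.84)),
    trans_butene = mk(rep("C", 4), 1:3, 2:4, c(1L, 2L, 1L),
                      dbstereo = list(pair = c(1L, 4L), distance = 3.87)),
    acetamide = mk(c("C", "C", "O", "N"), c(1, 2, 2), c(2, 3, 4),
                   c(1L, 2L, 1L)),
    methyl_acetate = mk(c("C", "C", "O", "O", "C"), c(1, 2, 2, 4), c(2, 3, 4, 5),
                        c(1L, 2L, 1L, 1L)),
    acetate = mk(c("C", "C", "O", "O"), c(1, 2, 2), c(2, 3, 4),
                 c(1L, 2L, 1L), charges = c(0L, 0L, 0L, -1L))
  )
}

template_pose <- function(template) {
  t <- template_library()[[template]]
  if (is.null(t)) stop("unknown template: ", template)
  mol_pose(t$elements, matrix(0, length(t$elements), 3), t$bonds,
           charges = t$charges, name = template)
}

signed_volume <- function(xyz, center, nbrs) {
  v <- sweep(xyz[nbrs, , drop = FALSE], 2, xyz[center, ])
  det(v)
}

#' Generate a valid embedded conformer for a template
#'
#' Distance-geometry embedding (with stereo enforcement: specified
#' tetrahedral centres by mirror correction, double-bond geometry by a
#' tight 1-4 distance constraint), hydrogen completion and UFF relaxation.
#' The result passes all intramolecular and energy checks at default
#' thresholds.
#'
#' @param template A name from [fixture_templates()].
#' @param seed Integer seed; embedding is deterministic given the seed.
#' @param relax_steps Relaxation step budget (default 500).
#' @return A [mol_pose()] with hydrogens and relaxed 3D coordinates.
#' @export
make_valid_pose <- function(template, seed = 1L, relax_steps = 500) {
  t <- template_library()[[template]]
  if (is.null(t)) stop("unknown template: ", template)
  mol <- template_pose(template)
  b <- bounds_matrix(mol)
  if (!is.null(t$dbstereo)) {
    p <- t$dbstereo$pair
    b$lower[p[1], p[2]] <- b$lower[p[2], p[1]] <- t$dbstereo$distance - 0.15
    b$upper[p[1], p[2]] <- b$upper[p[2], p[1]] <- t$dbstereo$distance + 0.15
  }
  for (attempt in seq_len(10)) {
    emb <- withr_seed(seed + 7919L * (attempt - 1L),
                      embed_conformer_retry(mol, b))
    if (embedding_violation(emb$xyz, b) > 0.5 && attempt < 10) next
    if (!is.null(t$chiral)) {
      s <- signed_volume(emb$xyz, t$chiral$center, t$chiral$nbrs)
      if (sign(s) != t$chiral$sign) emb$xyz[, 1] <- -emb$xyz[, 1]
    }
    relaxed <- tryCatch(
      ob_minimize(ob_add_hydrogens_batch(list(emb)), steps = relax_steps)[[1]],
      error = function(e) NULL)
    if (is.null(relaxed)) next
    ok <- outcome_passed(check_bond_lengths(relaxed)) &&
      outcome_passed(check_bond_angles(relaxed)) &&
      outcome_passed(check_internal_clash(relaxed))
    if (ok) {
      relaxed$name <- template
      relaxed$charges <- full_charges_after_h(mol, relaxed)
      return(relaxed)
    }
  }
  stop("embedding failed for template ", template, " after 10 attempts")
}

# hydrogen completion via Open Babel drops our formal charges (written as
# M CHG they survive; this guards against count mismatches)
full_charges_after_h <- function(orig, withH) {
  ch <- integer(n_atoms(withH))
  nh <- n_atoms(orig)
  ch[seq_len(min(nh, length(ch)))] <- orig$charges[seq_len(min(nh, length(ch)))]
  ch
}

# ---- distortions -----------------------------------------------------------

#' Apply a targeted single-defect distortion to a pose
#'
#' Each distortion kind is designed to violate one named validity check at
#' its default magnitude while leaving the other checks passing where the
#' defect is geometrically separable:
#'
#' * `bond_stretch` / `bond_compress`: scale one bond (default factors 1.4
#'   / 0.6) by translating the smaller fragment -> bond length check.
#' * `angle_bend`: close one bond angle (default to 60 degrees) -> bond
#'   angle check.
#' * `ring_buckle`: lift one aromatic ring atom out of plane (default
#'   0.8 Angstrom) -> aromatic ring planarity.
#' * `twist_double_bond`: rotate about an acyclic C=C (default 90
#'   degrees) -> double bond planarity.
#' * `stereo_flip`: mirror the molecule, inverting its specified
#'   tetrahedral centre -> tetrahedral chirality consistency (distances
#'   are preserved, so geometry checks still pass).
#' * `internal_fold`: drive chain torsions to fold two distant atoms
#'   together -> internal steric clash.
#' * `clash_translate`: rigid translation (toward a receptor) -> protein
#'   distance/overlap checks.
#' * `formula_edit`: mutate a terminal carbon to nitrogen -> molecular
#'   formula consistency (the bonds layers change with it; entangled).
#' * `bond_edit`: reconnect a bond (break one chain bond, join the chain
#'   ends) -> bonds consistency; the edited topology is re-embedded so
#'   geometry checks stay clean.
#'
#' @param mol A pose from [make_valid_pose()].
#' @param kind Distortion kind (see above).
#' @param magnitude Kind-specific magnitude; `NULL` uses the documented
#'   default.
#' @param target Kind-specific selector (bond index, atom index, triple,
#'   or translation vector); `NULL` picks the first applicable site.
#' @param seed Seed for re-embedding kinds.
#' @return The distorted [mol_pose()].
#' @export
distort <- function(mol, kind, magnitude = NULL, target = NULL, seed = 1L) {
  heavy <- strip_hydrogens(mol)
  switch(kind,
    bond_stretch = scale_bond(heavy, target, if (is.null(magnitude)) 1.4 else magnitude),
    bond_compress = scale_bond(heavy, target, if (is.null(magnitude)) 0.6 else magnitude),
    angle_bend = bend_angle(heavy, target, if (is.null(magnitude)) 60 else magnitude),
    ring_buckle = buckle_ring(heavy, target, if (is.null(magnitude)) 0.8 else magnitude),
    twist_double_bond = twist_db(heavy, if (is.null(magnitude)) 90 else magnitude),
    stereo_flip = reflect_pose(heavy),
    internal_fold = fold_chain(heavy),
    clash_translate = transform_pose(heavy, translation =
      if (is.null(target)) c(if (is.null(magnitude)) 5 else magnitude, 0, 0)
      else target),
    formula_edit = edit_formula(heavy),
    bond_edit = edit_bonds(heavy, seed),
    stop("unknown distortion kind: ", kind)
  )
}

# reflect through the molecule's own least-squares plane: inverts every
# tetrahedral centre while preserving all interatomic distances and
# moving atoms as little as possible (so geometry checks and the 2 A RMSD
# criterion still hold)
reflect_pose <- function(mol) {
  fp <- fit_plane(mol$xyz)
  proj <- as.numeric(sweep(mol$xyz, 2, colMeans(mol$xyz)) %*% fp$normal)
  mol$xyz <- mol$xyz - 2 * proj %*% t(fp$normal)
  mol
}

split_at_bond <- function(mol, i, j) {
  # atoms on j's side after cutting bond i-j; errors if i is reachable
  # from j without that bond (the bond closes a ring)
  adj <- adjacency_list(mol)
  seen <- rep(FALSE, n_atoms(mol))
  queue <- j; seen[j] <- TRUE
  while (length(queue) > 0) {
    a <- queue[1]; queue <- queue[-1]
    for (nb in adj[[a]]) {
      if (a == j && nb == i) next  # the cut bond itself
      if (nb == i) stop("bond is in a ring; fragment translation not applicable")
      if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
    }
  }
  which(seen)
}

scale_bond <- function(mol, target, factor) {
  k <- if (is.null(target)) {
    rings <- smallest_rings(mol)
    ring_atoms <- unlist(rings)
    in_ring <- vapply(seq_len(nrow(mol$bonds)), function(kk)
      any(vapply(rings, function(r) all(c(mol$bonds$i[kk], mol$bonds$j[kk]) %in% r), TRUE)),
      TRUE)
    cand <- which(!in_ring)
    if (length(cand) == 0) stop("no acyclic bond to scale")
    # prefer an unconjugated C-C single bond: conjugation-shortened bonds
    # (e.g. amide C-N) sit low in their bounds and need larger factors
    cc <- cand[mol$bonds$order[cand] == 1L &
               mol$elements[mol$bonds$i[cand]] == "C" &
               mol$elements[mol$bonds$j[cand]] == "C"]
    if (length(cc) > 0) cc[length(cc)] else cand[length(cand)]
  } else target
  i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
  side <- split_at_bond(mol, i, j)
  v <- mol$xyz[j, ] - mol$xyz[i, ]
  mol$xyz[side, ] <- sweep(mol$xyz[side, , drop = FALSE], 2, (factor - 1) * v, "+")
  mol
}

bend_angle <- function(mol, target, new_angle_deg) {
  if (is.null(target)) {
    adj <- adjacency_list(mol)
    j <- which(lengths(adj) >= 2)[1]
    target <- c(adj[[j]][1], j, adj[[j]][2])
  }
  i <- target[1]; j <- target[2]; k <- target[3]
  v1 <- mol$xyz[i, ] - mol$xyz[j, ]; v2 <- mol$xyz[k, ] - mol$xyz[j, ]
  cur <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  axis <- pracma_cross(v1, v2)
  if (sqrt(sum(axis^2)) < 1e-8) axis <- pracma_cross(v1, c(1, 0, 0))
  axis <- axis / sqrt(sum(axis^2))
  side <- split_at_bond(mol, j, k)
  ang <- (new_angle_deg - cur) * pi / 180
  R <- rotation_matrix(axis, ang)
  mol$xyz[side, ] <- sweep(sweep(mol$xyz[side, , drop = FALSE], 2, mol$xyz[j, ]) %*% t(R),
                           2, mol$xyz[j, ], "+")
  mol
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

rotation_matrix <- function(axis, angle) {
  c_ <- cos(angle); s <- sin(angle); C <- 1 - c_
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(x * x * C + c_, x * y * C - z * s, x * z * C + y * s,
           y * x * C + z * s, y * y * C + c_, y * z * C - x * s,
           z * x * C - y * s, z * y * C + x * s, z * z * C + c_),
         3, 3, byrow = TRUE)
}

buckle_ring <- function(mol, target, lift) {
  rings <- smallest_rings(mol)
  arom <- perceive_aromatic_rings(mol, rings)
  if (length(arom) == 0) stop("no aromatic ring to buckle")
  ring <- rings[[arom[1]]]
  a <- if (is.null(target)) ring[1] else target
  fp <- fit_plane(mol$xyz[ring, , drop = FALSE])
  mol$xyz[a, ] <- mol$xyz[a, ] + lift * fp$normal
  mol
}

twist_db <- function(mol, angle_deg) {
  rings <- smallest_rings(mol)
  b <- mol$bonds
  k <- NULL
  for (kk in which(b$order == 2L)) {
    i <- b$i[kk]; j <- b$j[kk]
    if (mol$elements[i] == "C" && mol$elements[j] == "C" &&
        !any(vapply(rings, function(r) all(c(i, j) %in% r), TRUE))) { k <- kk; break }
  }
  if (is.null(k)) stop("no acyclic C=C double bond to twist")
  i <- b$i[k]; j <- b$j[k]
  side <- split_at_bond(mol, i, j)
  axis <- mol$xyz[j, ] - mol$xyz[i, ]
  axis <- axis / sqrt(sum(axis^2))
  R <- rotation_matrix(axis, angle_deg * pi / 180)
  side <- setdiff(side, j)
  mol$xyz[side, ] <- sweep(sweep(mol$xyz[side, , drop = FALSE], 2, mol$xyz[j, ]) %*% t(R),
                           2, mol$xyz[j, ], "+")
  mol
}

# fold an acyclic chain by driving its rotatable torsions to bring the two
# chain ends into steric contact
fold_chain <- function(mol) {
  adj <- adjacency_list(mol)
  if (length(smallest_rings(mol)) > 0) stop("internal_fold needs an acyclic molecule")
  ends <- which(lengths(adj) == 1)
  if (length(ends) < 2) stop("no chain ends")
  e1 <- ends[1]; e2 <- ends[length(ends)]
  rotatable <- which(vapply(seq_len(nrow(mol$bonds)), function(k) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    lengths(adj)[i] > 1 && lengths(adj)[j] > 1 && mol$bonds$order[k] == 1L
  }, TRUE))
  obj <- function(angles) {
    m <- mol
    for (t in seq_along(rotatable)) {
      k <- rotatable[t]
      i <- m$bonds$i[k]; j <- m$bonds$j[k]
      side <- setdiff(split_at_bond(m, i, j), j)
      if (length(side) == 0) next
      axis <- m$xyz[j, ] - m$xyz[i, ]
      axis <- axis / sqrt(sum(axis^2))
      R <- rotation_matrix(axis, angles[t])
      m$xyz[side, ] <- sweep(sweep(m$xyz[side, , drop = FALSE], 2, m$xyz[j, ]) %*% t(R),
                             2, m$xyz[j, ], "+")
    }
    list(d = sqrt(sum((m$xyz[e1, ] - m$xyz[e2, ])^2)), mol = m)
  }
  if (length(rotatable) == 1) {
    fit <- stats::optimize(function(a) obj(a)$d, c(-pi, pi))
    return(obj(fit$minimum)$mol)
  }
  fit <- stats::optim(rep(0, length(rotatable)),
                      function(a) obj(a)$d, method = "Nelder-Mead",
                      control = list(maxit = 500))
  obj(fit$par)$mol
}

edit_formula <- function(mol) {
  adj <- adjacency_list(mol)
  term_c <- which(mol$elements == "C" & lengths(adj) == 1)
  if (length(term_c) == 0) {
    term_c <- which(mol$elements == "C")
    if (length(term_c) == 0) stop("no carbon to mutate")
  }
  mol$elements[term_c[1]] <- "N"
  mol
}

edit_bonds <- function(mol, seed) {
  adj <- adjacency_list(mol)
  ends <- which(lengths(adj) == 1)
  if (length(ends) < 2 || length(smallest_rings(mol)) > 0) {
    stop("bond_edit needs an acyclic chain")
  }
  # break an interior chain bond and reattach the detached fragment one
  # atom earlier, creating a branch: same formula, different
  # connectivity; re-embed so the geometry stays valid
  b <- mol$bonds
  mid <- which(b$order == 1L &
               lengths(adj)[b$i] > 1 & lengths(adj)[b$j] > 1)
  if (length(mid) == 0) stop("no interior bond to reconnect")
  k <- mid[ceiling(length(mid) / 2)]
  i <- b$i[k]; j <- b$j[k]
  anchor <- setdiff(adj[[i]], j)[1]
  b <- b[-k, , drop = FALSE]
  b <- rbind(b, data.frame(i = anchor, j = j, order = 1L))
  edited <- mol_pose(mol$elements, mol$xyz, b, mol$charges, mol$isotopes,
                     paste0(mol$name, "_bondedit"), mol$source_index)
  bm <- bounds_matrix(edited)
  emb <- withr_seed(seed, embed_conformer_retry(edited, bm))
  relaxed <- tryCatch(
    ob_minimize(ob_add_hydrogens_batch(list(emb)), steps = 500)[[1]],
    error = function(e) emb)
  relaxed
}

# ---- toy complex -----------------------------------------------------------

#' Generate a toy protein-ligand complex
#'
#' Builds an idealised 8-residue polyalanine helix fragment as the
#' receptor, optionally decorated with a Zn ion and an acetate group as
#' inorganic/organic cofactors near the binding groove, and places a
#' ligand conformer in a shallow groove at least 3.5 Angstrom from every
#' receptor atom (a crystal-like pose). The predicted-pose file repeats
#' the crystal-like pose; distorted variants are made with [distort()].
#'
#' @param seed Integer seed for the ligand conformer.
#' @param template Ligand template name (default `"butan2ol"`, the chiral
#'   template, so stereo distortions apply).
#' @param cofactors Include the Zn and acetate cofactor groups?
#' @param dir Directory to write `receptor.pdb`, `true.sdf`, `pred.sdf`
#'   into; `NULL` writes nothing.
#' @return List with `receptor_pdb`, `true_sdf`, `pred_sdf` (character
#'   vectors of file lines), `ligand` (the placed [mol_pose()]) and, if
#'   `dir` is given, the three `paths`.
#' @export
make_toy_complex <- function(seed = 1L, template = "butan2ol",
                             cofactors = TRUE, dir = NULL) {
  helix <- helix_atoms()
  lig <- make_valid_pose(template, seed = seed)
  # place the ligand along +x from the helix surface, min distance ~4.5 A
  lig$xyz <- sweep(lig$xyz, 2, colMeans(lig$xyz))
  offset <- c(max(helix$x) + 4.5 - min(lig$xyz[, 1]) +
                max(element_radius(lig$elements[lig$elements != "H"], "vdw")),
              mean(range(helix$y)), mean(range(helix$z)))
  lig <- transform_pose(lig, translation = offset)
  # nudge until every receptor-ligand distance exceeds 3.5 A
  repeat {
    d <- min_cross_dist(lig$xyz, cbind(helix$x, helix$y, helix$z))
    if (d >= 3.5) break
    lig <- transform_pose(lig, translation = c(0.5, 0, 0))
  }
  het <- NULL
  if (cofactors) {
    ligh <- lig$xyz[is_heavy(lig), , drop = FALSE]
    # push a cofactor group outward until its closest approach to the
    # ligand lies in the (3.0, 4.0) Angstrom proximity window
    place <- function(xyz, direction) {
      repeat {
        if (min_cross_dist(xyz, ligh) >= 3.0) return(xyz)
        xyz <- sweep(xyz, 2, 0.25 * direction, "+")
      }
    }
    zn <- place(matrix(colMeans(ligh) + c(0, 3.0, 0), 1), c(0, 1, 0))
    act0 <- rbind(c(0, 0, 0), c(1.50, 0, 0), c(2.10, 1.05, 0), c(2.10, -1.05, 0))
    act <- place(sweep(act0, 2, colMeans(ligh) + c(0, -3.0, -1), "+"),
                 c(0, -1, 0))
    het <- list(
      zn = data.frame(element = "Zn", x = zn[1], y = zn[2], z = zn[3],
                      resid = "ZN"),
      act = data.frame(element = c("C", "C", "O", "O"),
                       x = act[, 1], y = act[, 2], z = act[, 3],
                       resid = "ACT"))
  }
  pdb <- format_toy_pdb(helix, het)
  true_sdf <- write_sdf(lig)
  pred_sdf <- true_sdf
  out <- list(receptor_pdb = pdb, true_sdf = true_sdf, pred_sdf = pred_sdf,
              ligand = lig)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(dir, c("receptor.pdb", "true.sdf", "pred.sdf"))
    writeLines(pdb, paths[1]); writeLines(true_sdf, paths[2])
    writeLines(pred_sdf, paths[3])
    out$paths <- stats::setNames(paths, c("receptor", "true", "pred"))
  }
  out
}

min_cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(min(d2), 0))
}

# idealised alpha-helix backbone: rise 1.5 A, 100 degrees per residue,
# CA radius 2.3 A; N/C/O/CB placed at plausible offsets
helix_atoms <- function(n_res = 8) {
  out <- NULL
  for (k in seq_len(n_res)) {
    th <- (k - 1) * 100 * pi / 180
    ca <- c(2.3 * cos(th), 2.3 * sin(th), (k - 1) * 1.5)
    tang <- c(-sin(th), cos(th), 0.55); tang <- tang / sqrt(sum(tang^2))
    radial <- c(cos(th), sin(th), 0)
    nn <- ca - 1.46 * tang
    cc <- ca + 1.52 * tang
    oo <- cc + 1.23 * c(radial[1] * 0.3 - tang[1] * 0.2, radial[2] * 0.3 - tang[2] * 0.2, 0.9)
    cb <- ca + 1.53 * radial
    out <- rbind(out,
      data.frame(elety = c("N", "CA", "C", "O", "CB"),
                 element = c("N", "C", "C", "O", "C"),
                 x = c(nn[1], ca[1], cc[1], oo[1], cb[1]),
                 y = c(nn[2], ca[2], cc[2], oo[2], cb[2]),
                 z = c(nn[3], ca[3], cc[3], oo[3], cb[3]),
                 resno = k))
  }
  out
}

format_toy_pdb <- function(helix, het = NULL, with_waters = 0) {
  lines <- character(); serial <- 0L
  fmt <- function(type, serial, name, resid, chain, resno, x, y, z, el) {
    sprintf("%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            type, serial, name, resid, chain, resno, x, y, z, toupper(el))
  }
  for (r in seq_len(nrow(helix))) {
    serial <- serial + 1L
    lines <- c(lines, fmt("ATOM", serial, helix$elety[r], "ALA", "A",
                          helix$resno[r], helix$x[r], helix$y[r], helix$z[r],
                          helix$element[r]))
  }
  resno <- max(helix$resno)
  if (!is.null(het)) {
    for (g in het) {
      resno <- resno + 1L
      for (r in seq_len(nrow(g))) {
        serial <- serial + 1L
        nm <- paste0(toupper(g$element[r]), r)
        lines <- c(lines, fmt("HETATM", serial, nm, g$resid[r], "A", resno,
                              g$x[r], g$y[r], g$z[r], g$element[r]))
      }
    }
  }
  if (with_waters > 0) {
    for (w in seq_len(with_waters)) {
      serial <- serial + 1L; resno <- resno + 1L
      lines <- c(lines, fmt("HETATM", serial, "O", "HOH", "A", resno,
                            20 + w * 3, 20, 20, "O"))
    }
  }
  c(lines, "END")
}
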