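# Distance-geometry bounds and the intramolecular geometry checks.

test_that("bounds matrix brackets ideal geometry and satisfies its invariants", {
  b <- bounds_matrix(ethane_heavy())
  expect_lte(b$lower[1, 2], 1.53)
  expect_gte(b$upper[1, 2], 1.53)
  expect_lt(b$upper[1, 2] - b$lower[1, 2], 0.3)

  bb <- bounds_matrix(benzene_arom())
  expect_lte(bb$lower[1, 4], 2.78)  # para pair across the ring
  expect_gte(bb$upper[1, 4], 2.78)
  # topology-only: coordinates never enter
  moved <- benzene_arom()
  moved$xyz <- moved$xyz + 100
  expect_equal(bounds_matrix(moved)$lower, bb$lower)

  for (m in list(ethane_heavy(), benzene_arom(), cached_pose("butan2ol"),
                 cached_pose("methyl_acetate"))) {
    bm <- bounds_matrix(m)
    expect_true(all(bm$lower <= bm$upper + 1e-9))
    expect_true(all(bm$lower >= 0))
    expect_true(all(diag(bm$lower) == 0) && all(diag(bm$upper) == 0))
    expect_equal(bm$lower, t(bm$lower))
    expect_equal(bm$upper, t(bm$upper))
  }
})

test_that("bond length check fails stretched and compressed bonds and passes relaxed ones", {
  p <- propane_at()
  b <- bounds_matrix(p)
  expect_true(outcome_passed(check_bond_lengths(p, b)))

  stretched <- p
  stretched$xyz[1, 1] <- -(2.2 - 1.526)  # C1-C2 distance 2.2 A
  out <- check_bond_lengths(stretched, b)
  expect_false(outcome_passed(out))
  expect_equal(out$details$value, 2.2, tolerance = 1e-6)
  expect_lt(out$details$upper, 2.2)  # 1.25 * upper sits below the measurement

  compressed <- p
  compressed$xyz[1, 1] <- 0.526  # C1-C2 distance 1.0 A
  out2 <- check_bond_lengths(compressed, b)
  expect_false(outcome_passed(out2))
  expect_gt(out2$details$lower, 1.0)
})

test_that("angle check through the 1-3 surrogate distance flags a 60-degree bend", {
  b <- bounds_matrix(propane_at())
  expect_true(outcome_passed(check_bond_angles(propane_at(109.47), b)))
  expect_false(outcome_passed(check_bond_angles(propane_at(60), b)))
  # a fully linearised sp3 angle stays inside the 1.25 distance factor:
  # chord(180)/chord(109.47) = 1/sin(54.735) ~ 1.22 < 1.25
  expect_true(outcome_passed(check_bond_angles(propane_at(180), b)))
})

test_that("internal clash check flags folded chains but exempts 1-2/1-3 and ring pairs", {
  hx <- cached_pose("hexane")
  b <- bounds_matrix(hx)
  expect_true(outcome_passed(check_internal_clash(hx, b)))
  folded <- distort(hx, "internal_fold")
  out <- check_internal_clash(folded, b)
  expect_false(outcome_passed(out))
  expect_true(outcome_passed(check_bond_lengths(folded, b)))
  expect_true(outcome_passed(check_bond_angles(folded, b)))
  # benzene: every pair is bonded, angle-related or ring-constrained
  expect_true(outcome_passed(check_internal_clash(benzene_arom())))
})

test_that("plane fit equals an independent SVD solution and handles degeneracy", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0.4))
  fp <- fit_plane(sq)
  # independent least-squares fit via prcomp residuals
  pc <- stats::prcomp(sq)
  dev <- abs(pc$x[, 3])
  expect_equal(fp$max_dev, max(dev), tolerance = 1e-9)

  flat <- cbind(matrix(rnorm(20), 10, 2), 0)
  expect_equal(fit_plane(flat)$max_dev, 0, tolerance = 1e-12)
  coll <- cbind(seq_len(5), 2 * seq_len(5), 3 * seq_len(5))
  expect_equal(fit_plane(coll)$max_dev, 0, tolerance = 1e-9)
  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 1, 1))), "3 points")
})

test_that("planarity checks flag buckled rings and twisted double bonds only where in scope", {
  bz <- benzene_arom()
  expect_true(outcome_passed(check_ring_planarity(bz)))
  buck <- distort(bz, "ring_buckle")  # 0.8 A lift -> 0.38 A plane deviation
  out <- check_ring_planarity(buck)
  expect_false(outcome_passed(out))
  expect_gt(out$details$value, 0.25)

  # non-aromatic chair ring is out of scope for ring planarity
  expect_true(outcome_passed(check_ring_planarity(cached_pose("cyclohexane"))))

  tb <- cached_pose("trans_butene")
  expect_true(outcome_passed(check_double_bond_planarity(tb)))
  twisted <- distort(tb, "twist_double_bond")
  expect_false(outcome_passed(check_double_bond_planarity(twisted)))
  # aromatic-ring C=C bonds are exempt from the double-bond test
  expect_true(outcome_passed(check_double_bond_planarity(benzene_kekule())))
})

test_that("geometry verdicts are invariant under rigid motion and reindexing", {
  set.seed(11)
  for (m in list(cached_pose("butan2ol"), distort(cached_pose("hexane"), "bond_stretch"))) {
    heavy <- strip_hydrogens(m)
    b <- bounds_matrix(heavy)
    base <- c(outcome_passed(check_bond_lengths(heavy, b)),
              outcome_passed(check_bond_angles(heavy, b)),
              outcome_passed(check_internal_clash(heavy, b)))
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    R <- poseval:::rotation_matrix(ax, runif(1, 0, 2 * pi))
    moved <- transform_pose(heavy, R, rnorm(3, sd = 10))
    expect_identical(c(outcome_passed(check_bond_lengths(moved, b)),
                       outcome_passed(check_bond_angles(moved, b)),
                       outcome_passed(check_internal_clash(moved, b))), base)
    perm <- sample(length(heavy$elements))
    reord <- poseval:::reindex_pose(heavy, perm)
    b2 <- bounds_matrix(reord)
    expect_identical(c(outcome_passed(check_bond_lengths(reord, b2)),
                       outcome_passed(check_bond_angles(reord, b2)),
                       outcome_passed(check_internal_clash(reord, b2))), base)
  }
})

test_that("passing at a tolerance implies passing at any looser tolerance", {
  stretched <- distort(cached_pose("hexane"), "bond_stretch", magnitude = 1.22)
  b <- bounds_matrix(stretched)
  tols <- c(0.05, 0.15, 0.25, 0.40, 0.60)
  verdict <- vapply(tols, function(t)
    outcome_passed(check_bond_lengths(stretched, b, tolerance = t)), TRUE)
  expect_true(all(diff(as.integer(verdict)) >= 0))  # once passing, stays passing
  cl <- vapply(tols, function(t)
    outcome_passed(check_internal_clash(distort(cached_pose("hexane"), "internal_fold"),
                                        b, tolerance = t)), TRUE)
  expect_true(all(diff(as.integer(cl)) >= 0))
})

test_that("check verdicts equal a brute-force scan of every pair and triple", {
  # independent oracle in helper-oracles.R: classifies pairs from scratch
  oracle <- geometry_scan_oracle
  cases <- list(cached_pose("benzene"), cached_pose("hexane"),
                cached_pose("butan2ol"), cached_pose("methyl_acetate"),
                cached_pose("furan"), cached_pose("pyridine"),
                distort(cached_pose("hexane"), "bond_stretch"),
                distort(cached_pose("hexane"), "internal_fold"),
                distort(cached_pose("isobutane"), "angle_bend"),
                propane_at(60), propane_at(109.47))
  for (m in cases) {
    b <- bounds_matrix(m)
    got <- c(outcome_passed(check_bond_lengths(m, b)),
             outcome_passed(check_bond_angles(m, b)),
             outcome_passed(check_internal_clash(m, b)))
    expect_identical(got, oracle(m, b), label = m$name)
  }
})
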