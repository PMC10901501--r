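# Sanitisation and standard-InChI layer consistency.

test_that("sanitisation accepts valid molecules and rejects valence violations", {
  expect_true(outcome_passed(check_sanitises(benzene_kekule())))
  expect_true(outcome_passed(check_sanitises(benzene_arom())))

  # pentavalent neutral carbon: 5 single bonds
  pent <- mol_pose(rep("C", 6),
                   rbind(c(0, 0, 0), 1.5 * diag(3), c(-1.5, 0, 0), c(0, -1.5, 0)),
                   data.frame(i = 1, j = 2:6, order = 1L))
  out <- check_sanitises(pent)
  expect_false(outcome_passed(out))
  expect_match(out$details$description, "valence")

  # ammonium-type nitrogen: 4 bonds with +1 charge is fine
  nplus <- mol_pose(c("N", rep("C", 4)),
                    rbind(c(0, 0, 0), 1.5 * diag(3), c(-1.5, 0, 0)),
                    data.frame(i = 1, j = 2:5, order = 1L),
                    charges = c(1L, 0L, 0L, 0L, 0L))
  expect_true(outcome_passed(check_sanitises(nplus)))
  # ...but the same nitrogen without the charge is a violation
  n0 <- nplus; n0$charges[1] <- 0L
  expect_false(outcome_passed(check_sanitises(n0)))

  # aromatic bond outside a ring cannot kekulise
  openarom <- mol_pose(c("C", "C", "C"),
                       rbind(c(0, 0, 0), c(1.4, 0, 0), c(2.8, 0, 0)),
                       data.frame(i = c(1, 2), j = c(2, 3), order = c(4L, 1L)))
  expect_false(outcome_passed(check_sanitises(openarom)))
})

test_that("standardisation neutralises charges, strips isotopes and is idempotent", {
  acid <- cached_pose("methyl_acetate")  # ester: no ionisable site, sanity anchor
  ace <- cached_pose("acetate")          # carboxylate, charge -1
  # build the matching neutral acid by protonating: same heavy skeleton
  neutral <- strip_hydrogens(ace)
  neutral$charges[] <- 0L
  la <- standardise(ace)
  ln <- standardise(neutral)
  expect_identical(unclass(la), unclass(ln))
  expect_identical(la$q, "")
  expect_identical(la$p, "")

  iso <- ace
  iso$isotopes[1] <- 13L
  expect_identical(unclass(standardise(iso)), unclass(la))

  # idempotence: layers of a standardised molecule do not change when the
  # neutralised molecule is standardised again
  again <- neutralise_charges(ace)
  expect_identical(unclass(standardise(again)), unclass(la))

  expect_identical(unclass(standardise(acid)),
                   unclass(standardise(acid)))
})

test_that("layer comparison flags exactly the edited property", {
  bol <- cached_pose("butan2ol")
  same <- compare_consistency(bol, bol)
  expect_true(all(vapply(same, outcome_passed, TRUE)))

  # atom reordering leaves every verdict unchanged
  heavy <- strip_hydrogens(bol)
  perm <- rev(seq_along(heavy$elements))
  reord <- poseval:::reindex_pose(heavy, perm)
  cc <- compare_consistency(reord, bol)
  expect_true(all(vapply(cc, outcome_passed, TRUE)))

  # inverted stereocentre: chirality fails, the other three pass
  flip <- distort(bol, "stereo_flip")
  cc2 <- compare_consistency(flip, bol)
  expect_false(outcome_passed(cc2$tetrahedral_chirality))
  expect_true(outcome_passed(cc2$molecular_formula))
  expect_true(outcome_passed(cc2$bonds))
  expect_true(outcome_passed(cc2$double_bond_stereochemistry))

  # deleted bond: bonds check fails
  hx <- cached_pose("hexane")
  edited <- distort(hx, "bond_edit")
  cc3 <- compare_consistency(edited, hx)
  expect_false(outcome_passed(cc3$bonds))
  expect_true(outcome_passed(cc3$molecular_formula))

  # element mutation: formula fails
  cc4 <- compare_consistency(distort(hx, "formula_edit"), hx)
  expect_false(outcome_passed(cc4$molecular_formula))
})

test_that("cis and trans alkene isomers differ only in the /b layer", {
  cis <- cached_pose("cis_butene")
  tr <- cached_pose("trans_butene")
  cc <- compare_consistency(cis, tr)
  expect_false(outcome_passed(cc$double_bond_stereochemistry))
  expect_true(outcome_passed(cc$molecular_formula))
  expect_true(outcome_passed(cc$bonds))
  expect_true(outcome_passed(cc$tetrahedral_chirality))
})

test_that("primary ketimine double-bond stereo is removed before comparison", {
  # butan-2-imine CC(=N)CC with the N-H: E and Z forms (mirrored pose)
  # must standardise to identical layers
  path <- tempfile(fileext = ".sdf")
  # build E form geometrically: planar C=N with substituents
  el <- c("C", "C", "N", "C", "C")
  xyz <- rbind(c(-1.5, 0.9, 0), c(0, 0, 0), c(0, -1.3, 0.6),
               c(1.3, 0.7, 0), c(2.5, -0.2, 0))
  ket <- mol_pose(el, xyz,
                  data.frame(i = c(1, 2, 2, 4), j = c(2, 3, 4, 5),
                             order = c(1L, 2L, 1L, 1L)))
  mirror <- ket
  mirror$xyz[, 3] <- -mirror$xyz[, 3]
  mirror$xyz[, 1] <- mirror$xyz[, 1] + 0.01  # break exact coincidence
  expect_length(poseval:::find_primary_ketimines(ket), 1)
  le <- standardise(ket); lz <- standardise(mirror)
  expect_identical(le$b, lz$b)
  cc <- compare_consistency(ket, mirror)
  expect_true(outcome_passed(cc$double_bond_stereochemistry))
})
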