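# Synthetic fixture generation: valid conformers, targeted distortions,
# the toy complex.

test_that("every template embeds into a conformer passing all geometry checks", {
  for (tm in fixture_templates()) {
    p <- cached_pose(tm)
    expect_true(outcome_passed(check_sanitises(p)), label = tm)
    expect_true(outcome_passed(check_bond_lengths(p)), label = tm)
    expect_true(outcome_passed(check_bond_angles(p)), label = tm)
    expect_true(outcome_passed(check_internal_clash(p)), label = tm)
    expect_true(outcome_passed(check_ring_planarity(p)), label = tm)
    expect_true(outcome_passed(check_double_bond_planarity(p)), label = tm)
  }
})

test_that("embedding is deterministic in the seed and respects specified stereo", {
  a <- make_valid_pose("butan2ol", seed = 5)
  b <- make_valid_pose("butan2ol", seed = 5)
  expect_equal(a$xyz, b$xyz, tolerance = 1e-9)

  # chiral template: the specified parity is reproduced at every seed
  tpl <- poseval:::template_library()$butan2ol
  for (s in 1:5) {
    p <- strip_hydrogens(make_valid_pose("butan2ol", seed = s))
    sv <- poseval:::signed_volume(p$xyz, tpl$chiral$center, tpl$chiral$nbrs)
    expect_equal(sign(sv), tpl$chiral$sign, label = paste("seed", s))
  }
  # cis and trans alkenes embed on the intended side
  cis <- strip_hydrogens(cached_pose("cis_butene"))
  tr <- strip_hydrogens(cached_pose("trans_butene"))
  expect_lt(sqrt(sum((cis$xyz[1, ] - cis$xyz[4, ])^2)), 3.4)
  expect_gt(sqrt(sum((tr$xyz[1, ] - tr$xyz[4, ])^2)), 3.4)
})

test_that("each distortion kind trips its targeted check on compatible templates", {
  tc <- cached_toy_complex()
  rec <- load_receptor(tc$paths["receptor"])
  near <- cofactors_near_ligand(rec, tc$ligand)
  target_of <- list(
    bond_stretch = function(m) check_bond_lengths(m),
    bond_compress = function(m) check_bond_lengths(m),
    angle_bend = function(m) check_bond_angles(m),
    internal_fold = function(m) check_internal_clash(m))
  compatible <- list(
    bond_stretch = c("hexane", "butan2ol", "toluene", "methyl_acetate"),
    bond_compress = c("hexane", "butan2ol", "toluene", "methyl_acetate"),
    angle_bend = c("hexane", "isobutane", "butan2ol"),
    internal_fold = c("hexane"))
  for (kind in names(target_of)) {
    for (tm in compatible[[kind]]) {
      d <- distort(cached_pose(tm), kind)
      expect_false(outcome_passed(target_of[[kind]](d)),
                   label = paste(kind, "on", tm))
    }
  }
  # ring buckle / double-bond twist / stereo flip / topology edits
  expect_false(outcome_passed(check_ring_planarity(distort(cached_pose("benzene"), "ring_buckle"))))
  expect_false(outcome_passed(check_ring_planarity(distort(cached_pose("pyridine"), "ring_buckle"))))
  expect_false(outcome_passed(check_double_bond_planarity(
    distort(cached_pose("trans_butene"), "twist_double_bond"))))
  bol <- cached_pose("butan2ol")
  expect_false(outcome_passed(
    compare_consistency(distort(bol, "stereo_flip"), bol)$tetrahedral_chirality))
  hx <- cached_pose("hexane")
  expect_false(outcome_passed(
    compare_consistency(distort(hx, "formula_edit"), hx)$molecular_formula))
  expect_false(outcome_passed(
    compare_consistency(distort(hx, "bond_edit"), hx)$bonds))
  # clash translation onto the receptor trips the protein distance check
  crash <- distort(tc$ligand, "clash_translate", target = -c(9, 0, 0))
  out <- run_intermolecular_checks(crash, near)
  expect_false(outcome_passed(out$min_protein_ligand_distance))
})

test_that("geometrically separable distortions leave the untargeted checks passing", {
  hx <- cached_pose("hexane")
  stretch <- distort(hx, "bond_stretch")
  expect_true(outcome_passed(check_bond_angles(stretch)))
  expect_true(outcome_passed(check_internal_clash(stretch)))
  bend <- distort(hx, "angle_bend")
  expect_true(outcome_passed(check_bond_lengths(bend)))
  fold <- distort(hx, "internal_fold")
  expect_true(outcome_passed(check_bond_lengths(fold)))
  expect_true(outcome_passed(check_bond_angles(fold)))
  flip <- distort(cached_pose("butan2ol"), "stereo_flip")
  expect_true(outcome_passed(check_bond_lengths(flip)))
  expect_true(outcome_passed(check_bond_angles(flip)))
  expect_true(outcome_passed(check_internal_clash(flip)))
  buck <- distort(cached_pose("benzene"), "ring_buckle")
  expect_true(outcome_passed(check_bond_lengths(buck)))
  expect_true(outcome_passed(check_bond_angles(buck)))
})

test_that("the toy complex writes loadable files and a groove-placed ligand", {
  tc <- cached_toy_complex()
  rec <- load_receptor(tc$paths["receptor"])
  expect_gt(nrow(rec$protein_atoms), 30)
  expect_length(rec$organic_cofactors, 1)
  expect_length(rec$inorganic_cofactors, 1)
  lig <- load_ligands(tc$paths["true"])$poses[[1]]
  heavy <- strip_hydrogens(lig)
  d <- poseval:::min_cross_dist(heavy$xyz,
                                as.matrix(rec$protein_atoms[, c("x", "y", "z")]))
  expect_gte(d, 3.5)
  # without cofactors both groups are empty
  tc2 <- make_toy_complex(seed = 2, cofactors = FALSE,
                          dir = file.path(tempdir(), "toy-nocof"))
  rec2 <- load_receptor(tc2$paths["receptor"])
  expect_length(rec2$organic_cofactors, 0)
  expect_length(rec2$inorganic_cofactors, 0)
})
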