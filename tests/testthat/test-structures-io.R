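# SDF/PDB input, cofactor classification, radii table.

test_that("well-formed, corrupt and empty SDF records load with per-record status", {
  benz <- benzene_arom()
  path <- write_temp_sdf(benz)
  res <- load_ligands(path)
  expect_length(res$poses, 1)
  expect_equal(sum(res$poses[[1]]$elements != "H"), 6)
  expect_true(all(res$status$loaded))

  # corrupt record: bond references atom 99 of a 6-atom molecule; the
  # failure is a status, not an exception, and other records still load
  lines <- write_sdf(benz)
  bad <- sub("^  1  2", " 99  2", lines)
  path2 <- tempfile(fileext = ".sdf")
  writeLines(c(lines, bad), path2)
  res2 <- load_ligands(path2)
  expect_length(res2$poses, 1)
  expect_equal(res2$status$loaded, c(TRUE, FALSE))
  expect_match(res2$status$reason[2], "atom")

  empty <- tempfile(fileext = ".sdf")
  writeLines(character(), empty)
  res3 <- load_ligands(empty)
  expect_length(res3$poses, 0)
  expect_equal(nrow(res3$status), 0)

  expect_error(load_ligands(tempfile()), "not found")
})

test_that("SDF round trip preserves elements, charges, isotopes, orders and coordinates", {
  mol <- mol_pose(c("C", "C", "O", "O", "N"),
                  matrix(rnorm(15), 5, 3),
                  data.frame(i = c(1, 2, 2, 1), j = c(2, 3, 4, 5),
                             order = c(1L, 2L, 1L, 1L)),
                  charges = c(0L, 0L, 0L, -1L, 1L),
                  isotopes = c(13L, 0L, 0L, 0L, 0L),
                  name = "roundtrip")
  back <- load_ligands(write_temp_sdf(mol))$poses[[1]]
  expect_identical(back$elements, mol$elements)
  expect_identical(back$charges, mol$charges)
  expect_identical(back$isotopes, mol$isotopes)
  expect_identical(back$bonds$order, mol$bonds$order)
  expect_lt(max(abs(back$xyz - mol$xyz)), 1e-4)
})

test_that("V3000 records parse with charges", {
  v3 <- c("v3000 test", "", "",
          "  0  0  0  0  0  0  0  0  0  0999 V3000",
          "M  V30 BEGIN CTAB",
          "M  V30 COUNTS 3 2 0 0 0",
          "M  V30 BEGIN ATOM",
          "M  V30 1 C 0.0 0.0 0.0 0",
          "M  V30 2 C 1.5 0.0 0.0 0",
          "M  V30 3 O 2.3 1.1 0.0 0 CHG=-1",
          "M  V30 END ATOM",
          "M  V30 BEGIN BOND",
          "M  V30 1 1 1 2",
          "M  V30 2 1 2 3",
          "M  V30 END BOND",
          "M  V30 END CTAB",
          "M  END", "$$$$")
  path <- tempfile(fileext = ".sdf")
  writeLines(v3, path)
  res <- load_ligands(path)
  expect_true(res$status$loaded)
  expect_identical(res$poses[[1]]$elements, c("C", "C", "O"))
  expect_identical(res$poses[[1]]$charges, c(0L, 0L, -1L))
})

test_that("receptor atoms partition into protein/organic/inorganic with waters dropped", {
  helix <- poseval:::helix_atoms(3)
  het <- list(
    zn = data.frame(element = "Zn", x = 10, y = 0, z = 0, resid = "ZN"),
    sf4 = data.frame(element = c("Fe", "Fe", "S", "S"),
                     x = c(14, 15, 14, 15), y = c(0, 1, 1, 0), z = 0,
                     resid = "SF4"),
    hem_like = data.frame(element = c("C", "N", "Fe"),
                          x = c(20, 21, 22), y = 0, z = 0, resid = "HEM"))
  pdb <- poseval:::format_toy_pdb(helix, het, with_waters = 5)
  path <- tempfile(fileext = ".pdb")
  writeLines(pdb, path)
  rec <- load_receptor(path)
  expect_equal(nrow(rec$protein_atoms), nrow(helix))
  expect_length(rec$organic_cofactors, 1)   # HEM-like: contains carbon
  expect_length(rec$inorganic_cofactors, 2) # Zn ion and Fe/S cluster
  expect_equal(rec$n_waters_removed, 5)
  expect_equal(unname(rec$chains["A"]), "AAA")
  # partition property: protein + cofactor + water atoms = records parsed
  n_records <- sum(grepl("^(ATOM|HETATM)", pdb))
  n_classified <- nrow(rec$protein_atoms) +
    sum(vapply(rec$organic_cofactors, nrow, 1L)) +
    sum(vapply(rec$inorganic_cofactors, nrow, 1L)) + rec$n_waters_removed
  expect_equal(n_classified, n_records)
})

test_that("cofactor proximity filter respects the cutoff and is monotone in it", {
  lig <- mol_pose("C", matrix(c(0, 0, 0), 1),
                  data.frame(i = integer(), j = integer(), order = integer()))
  helix <- poseval:::helix_atoms(3)
  helix$x <- helix$x - 50  # park the protein far away
  het <- list(a = data.frame(element = "Zn", x = 3.0, y = 0, z = 0, resid = "ZN"),
              b = data.frame(element = "Mg", x = 4.5, y = 0, z = 0, resid = "MG"),
              c = data.frame(element = "Ca", x = 3.9, y = 0, z = 0, resid = "CA"),
              d = data.frame(element = "K", x = 4.1, y = 0, z = 0, resid = "K"))
  path <- tempfile(fileext = ".pdb")
  writeLines(poseval:::format_toy_pdb(helix, het), path)
  rec <- load_receptor(path)
  near <- cofactors_near_ligand(rec, lig, 4.0)
  kept <- vapply(near$inorganic_cofactors, function(g) g$resid[1], "")
  expect_setequal(kept, c("ZN", "CA"))  # 3.0 and 3.9 in; 4.1 and 4.5 out
  # monotone: every group kept at cutoff c1 is kept at c2 >= c1
  for (cuts in list(c(3.5, 4.0), c(4.0, 4.2), c(2.0, 10))) {
    k1 <- vapply(cofactors_near_ligand(rec, lig, cuts[1])$inorganic_cofactors,
                 function(g) g$resid[1], "")
    k2 <- vapply(cofactors_near_ligand(rec, lig, cuts[2])$inorganic_cofactors,
                 function(g) g$resid[1], "")
    expect_true(all(k1 %in% k2))
  }
})

test_that("radii table covers the required elements with vdW > covalent", {
  r <- radii_table()
  need <- c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I",
            "Na", "Mg", "K", "Ca", "Mn", "Fe", "Co", "Ni", "Cu", "Zn")
  expect_true(all(need %in% r$element))
  expect_true(all(r$vdw > r$covalent))
  expect_true(all(r$covalent > 0))
  expect_error(element_radius("Xx"), "no radius")
})
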