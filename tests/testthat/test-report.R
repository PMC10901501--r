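# Orchestration: modes, aggregate verdict, waterfall and report output.

test_that("default configuration carries the documented thresholds", {
  cfg <- poseval_config()
  expect_equal(cfg$bond_tolerance, 0.25)
  expect_equal(cfg$angle_tolerance, 0.25)
  expect_equal(cfg$clash_tolerance, 0.30)
  expect_equal(cfg$planarity_threshold, 0.25)
  expect_equal(cfg$energy_ratio_threshold, 100)
  expect_equal(cfg$ensemble_size, 50)
  expect_equal(cfg$relax_iterations, 200)
  expect_equal(cfg$distance_factor, 0.75)
  expect_equal(cfg$overlap_threshold, 0.075)
  expect_equal(cfg$overlap_scale_organic, 0.8)
  expect_equal(cfg$overlap_scale_inorganic, 0.5)
  expect_equal(cfg$cofactor_cutoff, 4.0)
  expect_equal(cfg$rmsd_threshold, 2.0)
  expect_error(poseval_config(bogus = 1), "unknown")

  f <- tempfile()
  writeLines(c("# overrides", "energy_ratio_threshold = 7", "rmsd_threshold=1.5"), f)
  over <- read_config(f)
  expect_equal(over$energy_ratio_threshold, 7)
  expect_equal(over$rmsd_threshold, 1.5)
  expect_equal(over$distance_factor, 0.75)  # untouched defaults remain
})

test_that("run modes select the documented check subsets", {
  expect_equal(run_modes("full"), check_names())
  dock <- run_modes("dock")
  expect_false(any(c("molecular_formula", "tetrahedral_chirality") %in% dock))
  expect_true("min_protein_ligand_distance" %in% dock)
  mol <- run_modes("mol")
  expect_false(any(grepl("protein|cofactor", mol)))
  expect_true(all(c("sanitisation", "bond_lengths", "energy_ratio") %in% mol))
  # full = union of the others plus consistency (and RMSD is reported)
  expect_setequal(setdiff(check_names(), union(dock, mol)),
                  c("molecular_formula", "bonds", "tetrahedral_chirality",
                    "double_bond_stereochemistry"))
})

test_that("a crystal-like pose is fully valid and a planted batch attributes first failures", {
  tc <- cached_toy_complex()
  res <- bust(tc$paths["pred"], tc$paths["true"], tc$paths["receptor"])
  r <- res[[1]]
  expect_true(r$pose_valid)
  expect_lt(r$rmsd, 1e-6)
  tab <- bust_table(res)
  expect_true(all(unlist(tab[, check_names()])))

  # batch with planted defects: crystal-like + stereo flip + stretch + clash
  flip <- distort(tc$ligand, "stereo_flip")
  stretch <- distort(tc$ligand, "bond_stretch")
  crash <- distort(tc$ligand, "clash_translate", target = -c(9, 0, 0))
  batch <- write_temp_sdf(list(tc$ligand, flip, stretch, crash))
  res2 <- bust(batch, tc$paths["true"], tc$paths["receptor"])
  wf <- waterfall(res2)
  expect_equal(wf$total, 4)
  expect_equal(wf$final_pass, 1)
  # conservation: final passes + introduced failures = total
  expect_equal(wf$final_pass + sum(wf$steps$failures_introduced), wf$total)
  got <- wf$steps$failures_introduced[match(
    c("tetrahedral_chirality", "bond_lengths", "min_protein_ligand_distance"),
    wf$steps$check)]
  expect_equal(got, c(1L, 1L, 1L))
})

test_that("a pose failing several checks is attributed to the first in report order", {
  rows <- list(
    list(name = "a", applicable = check_names(),
         outcomes = list(file_loads = check_outcome("file_loads", TRUE),
                         sanitisation = check_outcome("sanitisation", FALSE,
                           poseval:::detail_row("planted", NA_real_)),
                         internal_steric_clash = check_outcome("internal_steric_clash", FALSE,
                           poseval:::detail_row("planted", NA_real_))),
         pose_valid = FALSE))
  wf <- waterfall(rows)
  expect_equal(wf$steps$failures_introduced[wf$steps$check == "sanitisation"], 1L)
  expect_equal(sum(wf$steps$failures_introduced), 1L)
  # empty input: zero summary
  wf0 <- waterfall(list())
  expect_equal(wf0$total, 0); expect_equal(wf0$final_pass, 0)
})

test_that("an unloadable record fails loading without aborting the batch", {
  tc <- cached_toy_complex()
  lines <- readLines(tc$paths["pred"])
  bad <- sub("^  1  2", " 88  2", lines)
  path <- tempfile(fileext = ".sdf")
  writeLines(c(lines, bad), path)
  res <- bust(path, tc$paths["true"], tc$paths["receptor"])
  expect_length(res, 2)
  expect_true(res[[1]]$pose_valid)
  expect_false(res[[2]]$pose_valid)
  expect_false(isTRUE(res[[2]]$outcomes$file_loads$passed))
  wf <- waterfall(res)
  expect_equal(wf$steps$failures_introduced[wf$steps$check == "file_loads"], 1L)
})

test_that("reports are deterministic: same inputs and seed give byte-identical CSV", {
  tc <- cached_toy_complex()
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_report(bust(tc$paths["pred"], tc$paths["true"], tc$paths["receptor"]), p1)
  write_report(bust(tc$paths["pred"], tc$paths["true"], tc$paths["receptor"]), p2)
  expect_identical(readLines(p1), readLines(p2))
  long <- bust_table(bust(tc$paths["pred"], tc$paths["true"], tc$paths["receptor"]),
                     "long")
  expect_equal(nrow(long), 18)
  expect_true(all(long$passed))
})

test_that("mol mode validates a bare conformer with consistency and RMSD absent", {
  pose <- cached_pose("methyl_acetate")
  path <- write_temp_sdf(pose)
  res <- bust(path, mode = "mol")
  r <- res[[1]]
  expect_true(r$pose_valid)
  expect_true(is.na(r$rmsd))
  tab <- bust_table(res)
  expect_true(is.na(tab$molecular_formula))
  expect_true(is.na(tab$min_protein_ligand_distance))
  expect_true(tab$bond_lengths)
})
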