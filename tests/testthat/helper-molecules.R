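# Shared in-code fixtures: small molecules built directly as graphs plus
# cached embedded poses (deterministic, so caching is safe).

regular_hexagon <- function(side = 1.39) {
  t(sapply(0:5, function(k) side * c(cos(k * pi / 3), sin(k * pi / 3), 0)))
}

benzene_arom <- function() {
  mol_pose(rep("C", 6), regular_hexagon(),
           data.frame(i = 1:6, j = c(2:6, 1), order = 4L), name = "benzene")
}

benzene_kekule <- function() {
  mol_pose(rep("C", 6), regular_hexagon(),
           data.frame(i = 1:6, j = c(2:6, 1), order = rep(c(1L, 2L), 3)),
           name = "benzene")
}

propane_at <- function(theta_deg = 109.47, b = 1.526) {
  th <- theta_deg * pi / 180
  mol_pose(rep("C", 3),
           rbind(c(0, 0, 0), c(b, 0, 0),
                 c(b - b * cos(th), b * sin(th), 0)),
           data.frame(i = c(1, 2), j = c(2, 3), order = 1L), name = "propane")
}

ethane_heavy <- function(d = 1.53) {
  mol_pose(c("C", "C"), rbind(c(0, 0, 0), c(d, 0, 0)),
           data.frame(i = 1, j = 2, order = 1L), name = "ethane")
}

hexane_graph <- function() {
  mol_pose(rep("C", 6), matrix(0, 6, 3),
           data.frame(i = 1:5, j = 2:6, order = 1L), name = "hexane")
}

# cached deterministic embedded poses (shared across test files)
.pose_cache <- new.env()
cached_pose <- function(template, seed = 42) {
  key <- paste(template, seed)
  if (is.null(.pose_cache[[key]])) {
    .pose_cache[[key]] <- make_valid_pose(template, seed = seed)
  }
  .pose_cache[[key]]
}

.ens_cache <- new.env()
cached_ensemble <- function(template, seed = 42, n = 50) {
  key <- paste(template, seed, n)
  if (is.null(.ens_cache[[key]])) {
    .ens_cache[[key]] <- conformer_ensemble(cached_pose(template), n = n, seed = seed)
  }
  .ens_cache[[key]]
}

.toy_cache <- new.env()
cached_toy_complex <- function(seed = 4) {
  key <- as.character(seed)
  if (is.null(.toy_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("toy", seed))
    .toy_cache[[key]] <- make_toy_complex(seed = seed, dir = dir)
  }
  .toy_cache[[key]]
}

write_temp_sdf <- function(mols, name = "mols") {
  path <- tempfile(paste0(name, "-"), fileext = ".sdf")
  writeLines(write_sdf(mols), path)
  path
}
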