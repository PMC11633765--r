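# shared fixtures, built once per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# a default-scale cohort (14 per group, 300 frames) plus a fitted pipeline
default_fixture <- function() cached("default_fixture", {
  cfg <- sim_config(rng_seed = 101)
  coh <- generate_cohort(cfg)
  pl <- run_cap_pipeline(coh, k = 3, rng_seed = 102)
  list(cfg = cfg, cohort = coh, pipeline = pl)
})

# a small cohort for cheap end-to-end checks
small_cohort <- function(rng_seed = 11, n_per_group = 3)
  generate_cohort(sim_config(n_per_group = n_per_group, rng_seed = rng_seed))

# minimal volume series: deterministic values unless data given
toy_series <- function(n_frames = 20, grid = c(4, 4, 2), data = NULL,
                       tr = 1.3) {
  vi <- grid_voxel_index(grid)
  if (is.null(data)) {
    set.seed(99)
    data <- matrix(rnorm(n_frames * nrow(vi)), n_frames, nrow(vi))
  }
  volume_series(data, tr = tr, voxel_index = vi, grid = grid)
}

# independent run-length-encoding oracle for entries/durations
rle_oracle <- function(labels, k) {
  runs <- list(); cur <- NULL; len <- 0
  for (v in c(labels, NA)) {
    if (!is.null(cur) && (is.na(v) || v != cur)) {
      runs[[length(runs) + 1]] <- c(cur, len); len <- 0
    }
    if (is.na(v)) break
    if (len == 0) cur <- v
    len <- len + 1
  }
  lens <- vapply(runs, `[`, 1.0, 2)[vapply(runs, `[`, 1.0, 1) == k]
  list(entries = length(lens), mean_len = if (length(lens)) mean(lens) else NA)
}
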