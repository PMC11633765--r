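#' Simulation configuration for a synthetic CAP cohort
#'
#' Defines the generative model used to validate the pipeline end-to-end: a
#' latent first-order Markov chain per subject over a quiescent baseline state
#' plus `k_true` co-activation states, each state painting a smooth spatial
#' pattern (with positive loading on a small seed nucleus) on top of Gaussian
#' noise. Two groups differ only through their transition matrices; by default
#' the "patient" group gets a boosted state self-transition (persistence)
#' probability.
#'
#' The defaults mirror a two-group resting-state study: 14 subjects per group,
#' 300 frames at TR = 1.3 s, three planted co-activation patterns.
#'
#' @param n_per_group subjects per group (default 14).
#' @param n_frames frames per subject (default 300).
#' @param tr repetition time in seconds (default 1.3).
#' @param grid 3D grid dimensions (default c(12, 12, 8)).
#' @param k_true number of planted co-activation states (default 3).
#' @param seed_voxels indices (into the full-grid voxel ordering) of the
#'   synthetic seed nucleus; default is a small 2x2x2 block deep in the grid.
#' @param transition_matrix_by_group named list (`control`, `patient`) of
#'   (k_true+1) x (k_true+1) row-stochastic matrices over
#'   (baseline, state_1..state_k); default from
#'   [default_transition_matrices()].
#' @param pattern_amplitude signal amplitude of the planted patterns
#'   (default 1).
#' @param seed_gain extra positive loading every pattern puts on the seed
#'   voxels (default 1); scale it down on very small grids where the shared
#'   seed block would correlate the patterns above the separability limit.
#' @param noise_sd SD of i.i.d. Gaussian voxel noise (default 0.5).
#' @param motion_spike_prob per-frame probability of a translation jump large
#'   enough to exceed a 0.5 mm framewise-displacement threshold (default 0.05).
#' @param rng_seed integer seed; fans out to fixed per-subject substreams.
#' @param confound_effect optional named list of additive group effects on
#'   covariates (e.g. `list(bdi = 6)` adds 6 to patients' BDI scores) for
#'   testing covariate adjustment under confounding. Default none: covariates
#'   are group-independent.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 14L, n_frames = 300L, tr = 1.3,
                       grid = c(12L, 12L, 8L), k_true = 3L,
                       seed_voxels = NULL,
                       transition_matrix_by_group = NULL,
                       pattern_amplitude = 1, noise_sd = 0.5,
                       seed_gain = 1, motion_spike_prob = 0.05, rng_seed = 1L,
                       confound_effect = NULL) {
  grid <- as.integer(grid)
  k_true <- as.integer(k_true)
  if (length(grid) != 3L || any(grid < 4L))
    stop("'grid' must be 3 integers, each >= 4")
  if (k_true < 1L) stop("'k_true' must be >= 1")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (motion_spike_prob < 0 || motion_spike_prob > 1)
    stop("'motion_spike_prob' must be a probability")
  if (is.null(seed_voxels)) seed_voxels <- default_seed_voxels(grid)
  seed_voxels <- as.integer(seed_voxels)
  if (length(seed_voxels) == 0L || any(seed_voxels < 1L) ||
      any(seed_voxels > prod(grid)))
    stop("'seed_voxels' must be a nonempty set of indices inside the grid")
  if (is.null(transition_matrix_by_group))
    transition_matrix_by_group <- default_transition_matrices(k_true)
  for (g in names(transition_matrix_by_group))
    validate_transition_matrix(transition_matrix_by_group[[g]], k_true + 1L, g)
  structure(
    list(n_per_group = as.integer(n_per_group), n_frames = as.integer(n_frames),
         tr = tr, grid = grid, k_true = k_true, seed_voxels = seed_voxels,
         transition_matrix_by_group = transition_matrix_by_group,
         pattern_amplitude = pattern_amplitude, noise_sd = noise_sd,
         seed_gain = seed_gain, motion_spike_prob = motion_spike_prob,
         rng_seed = as.integer(rng_seed), confound_effect = confound_effect),
    class = "sim_config"
  )
}

validate_transition_matrix <- function(P, size, label = "") {
  P <- as.matrix(P)
  if (nrow(P) != size || ncol(P) != size)
    stop("transition matrix '", label, "' must be ", size, " x ", size)
  if (any(P < 0) || any(!is.finite(P)))
    stop("transition matrix '", label, "' has negative or non-finite entries")
  if (any(abs(rowSums(P) - 1) > 1e-12))
    stop("transition matrix '", label, "' rows must sum to 1 (tolerance 1e-12)")
  invisible(P)
}

default_seed_voxels <- function(grid) {
  # a 2x2x2 nucleus low in the grid, loosely "brainstem-like"
  cx <- floor(grid[1] / 2); cy <- floor(grid[2] / 2)
  idx <- expand.grid(x = cx + 0:1, y = cy + 0:1, z = 2:3)
  as.integer(idx$x + grid[1] * (idx$y - 1L) + grid[1] * grid[2] * (idx$z - 1L))
}

#' Default generative transition matrices for the two groups
#'
#' Baseline-dominated chains: from baseline the chain enters one of the
#' `k_true` states with small probability; states persist for a few frames
#' before returning to baseline. The patient group gets its state
#' self-transition probabilities boosted by `diagonal_boost` (taken out of the
#' return-to-baseline mass), i.e. a pure "state persistence" effect.
#'
#' @param k_true number of co-activation states.
#' @param diagonal_boost added to each state's self-transition probability in
#'   the patient group (default 0.10).
#' @return Named list with `control` and `patient` row-stochastic matrices,
#'   states ordered (baseline, state_1..state_k).
#' @export
default_transition_matrices <- function(k_true, diagonal_boost = 0.10) {
  k <- as.integer(k_true)
  build <- function(stay) {
    P <- matrix(0, k + 1L, k + 1L)
    P[1, 1] <- 0.82
    P[1, -1] <- 0.18 / k
    cross <- if (k > 1) 0.03 else 0
    for (s in seq_len(k)) {
      r <- s + 1L
      P[r, r] <- stay
      if (k > 1) P[r, 1 + setdiff(seq_len(k), s)] <- cross
      P[r, 1] <- 1 - stay - cross * (k - 1L)
    }
    dimnames(P) <- list(states = c("baseline", paste0("state_", seq_len(k))),
                        c("baseline", paste0("state_", seq_len(k))))
    P
  }
  list(control = build(0.50), patient = build(0.50 + diagonal_boost))
}

#' Planted co-activation patterns
#'
#' Builds `k_true` smooth spatial maps on the configured grid: each a Gaussian
#' activation blob at a distinct location plus a common positive loading on
#' the seed nucleus (so that seed activity gates all states, as the frame
#' selection stage assumes). Deterministic given the configuration.
#'
#' @param config a [sim_config()].
#' @return List of `k_true` numeric vectors over the full-grid voxel ordering;
#'   pairwise spatial correlation below 0.5 by construction (checked).
#' @export
make_patterns <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- config$grid; k <- config$k_true
  vi <- grid_voxel_index(grid)
  centers_frac <- list(c(.28, .28, .70), c(.72, .72, .70), c(.28, .72, .35),
                       c(.72, .28, .35), c(.50, .50, .80), c(.50, .22, .60),
                       c(.22, .50, .25), c(.78, .50, .60))
  if (k > length(centers_frac))
    stop("grid layout supports at most ", length(centers_frac), " patterns")
  sigma <- min(grid) / 5
  pats <- vector("list", k)
  for (j in seq_len(k)) {
    ctr <- 1 + centers_frac[[j]] * (grid - 1)
    d2 <- (vi[, 1] - ctr[1])^2 + (vi[, 2] - ctr[2])^2 + (vi[, 3] - ctr[3])^2
    p <- exp(-d2 / (2 * sigma^2))
    p[config$seed_voxels] <- p[config$seed_voxels] + config$seed_gain
    # zero spatial mean: real co-activation maps have balanced positive and
    # negative deflections, so the global signal carries no state information
    pats[[j]] <- p - mean(p)
  }
  if (k > 1) {
    cc <- stats::cor(do.call(cbind, pats))
    if (max(cc[upper.tri(cc)]) >= 0.5)
      stop("grid too small to place ", k, " separated patterns ",
           "(max pairwise correlation ", round(max(cc[upper.tri(cc)]), 3), ")")
  }
  pats
}

#' Simulate a latent state sequence
#'
#' First-order Markov chain over (baseline, state_1..state_k), started from
#' the stationary distribution of the group's transition matrix.
#'
#' @param config a [sim_config()].
#' @param group `"control"` or `"patient"` (any name present in
#'   `config$transition_matrix_by_group`).
#' @param n_frames chain length; defaults to `config$n_frames`.
#' @return Integer vector of length `n_frames` with 0 = baseline,
#'   1..k_true = co-activation states.
#' @export
simulate_state_sequence <- function(config, group, n_frames = config$n_frames) {
  stopifnot(inherits(config, "sim_config"))
  P <- config$transition_matrix_by_group[[group]]
  if (is.null(P)) stop("no transition matrix configured for group '", group, "'")
  P <- validate_transition_matrix(P, config$k_true + 1L, group)
  m <- nrow(P)
  pi0 <- stationary_distribution(P)
  s <- integer(n_frames)
  s[1] <- sample.int(m, 1L, prob = pi0)
  for (t in seq_len(n_frames - 1L))
    s[t + 1L] <- sample.int(m, 1L, prob = P[s[t], ])
  s - 1L
}

# left eigenvector of P for eigenvalue 1, normalized to a distribution
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

#' Render a volume series from a latent state sequence
#'
#' Frame t equals `pattern_amplitude * pattern[state_t]` plus i.i.d. Gaussian
#' noise; baseline frames are pure noise. Also fabricates realistic-shaped
#' nuisance inputs: a 6-column motion-parameter table whose translation track
#' jumps by 0.6 mm at spike frames (guaranteeing framewise displacement above
#' the 0.5 mm scrubbing threshold there), plus white-matter/CSF/global
#' nuisance time courses.
#'
#' @param config a [sim_config()].
#' @param truth list with `state_labels` (integer, 0 = baseline) and
#'   `patterns` (as from [make_patterns()]).
#' @return List with `series` (a [volume_series()]), `motion` (frames x 6
#'   matrix: trans_x/y/z in mm, rot_x/y/z in radians), and `nuisance`
#'   (data.frame wm, csf, global).
#' @export
render_series <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(truth$state_labels)
  vi <- grid_voxel_index(config$grid)
  V <- nrow(vi)
  Y <- matrix(stats::rnorm(n * V, sd = config$noise_sd), n, V)
  for (t in seq_len(n)) {
    s <- truth$state_labels[t]
    if (s > 0L)
      Y[t, ] <- Y[t, ] + config$pattern_amplitude * truth$patterns[[s]]
  }
  # motion: slow jitter random walk + step jumps at spike frames
  jitter <- matrix(stats::rnorm(n * 6, sd = c(rep(0.004, 3), rep(5e-5, 3))[
    rep(1:6, each = n)]), n, 6)
  motion <- apply(jitter, 2, cumsum)
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  spikes <- which(stats::runif(n) < config$motion_spike_prob)
  spikes <- spikes[spikes > 1L]
  for (t in spikes)
    motion[t:n, "trans_x"] <- motion[t:n, "trans_x"] +
      0.6 * sample(c(-1, 1), 1L)
  nuisance <- data.frame(
    wm = as.numeric(stats::filter(stats::rnorm(n), 0.5, "recursive")),
    csf = as.numeric(stats::filter(stats::rnorm(n), 0.5, "recursive")),
    global = rowMeans(Y)
  )
  series <- volume_series(Y, tr = config$tr, voxel_index = vi,
                          grid = config$grid)
  list(series = series, motion = motion, nuisance = nuisance,
       spike_frames = spikes)
}

#' Generate a synthetic two-group cohort
#'
#' Produces per-subject bundles (volume series, motion and nuisance tables,
#' latent ground truth) and a cohort covariates table on the scale of a
#' typical clinical resting-state study (age 20-58, positive depression and
#' state-anxiety questionnaire scores, a binary psychotropic-medication flag,
#' and an overdispersed recent-seizure count for patients). Covariates are
#' drawn independently of group unless `config$confound_effect` requests a
#' shift. All randomness derives from `config$rng_seed` through fixed
#' per-subject substreams, so regeneration is exactly reproducible.
#'
#' @param config a [sim_config()].
#' @return Object of class `cap_cohort`: list with `subjects` (each having
#'   `id`, `group`, `series`, `motion`, `nuisance`, `truth`), `covariates`
#'   (data.frame: subject_id, group, age, sex, medication, bdi, stai_s,
#'   seizure_count), `patterns`, and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  patterns <- make_patterns(config)
  groups <- rep(c("control", "patient"), each = config$n_per_group)
  n_sub <- length(groups)
  subjects <- vector("list", n_sub)
  cov_rows <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    set.seed((config$rng_seed + 7919L * i) %% .Machine$integer.max)
    g <- groups[i]
    labels <- simulate_state_sequence(config, g)
    truth <- list(state_labels = labels, patterns = patterns)
    rend <- render_series(config, truth)
    truth$motion_params <- rend$motion
    truth$spike_frames <- rend$spike_frames
    id <- sprintf("sub-%02d", i)
    subjects[[i]] <- list(id = id, group = g, series = rend$series,
                          motion = rend$motion, nuisance = rend$nuisance,
                          truth = truth)
    shift <- function(name) {
      ce <- config$confound_effect
      if (!is.null(ce[[name]]) && g == "patient") ce[[name]] else 0
    }
    cov_rows[[i]] <- data.frame(
      subject_id = id, group = g,
      age = sample(20:58, 1L) + shift("age"),
      sex = sample(c("F", "M"), 1L, prob = c(0.79, 0.21)),
      medication = stats::rbinom(1L, 1L, min(1, 0.25 + shift("medication"))),
      bdi = round(pmax(0, stats::rnorm(1, 8, 7) + shift("bdi"))),
      stai_s = round(pmax(20, stats::rnorm(1, 35, 9) + shift("stai_s"))),
      seizure_count = if (g == "patient")
        stats::rnbinom(1L, size = 0.25, mu = 6.5) else NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(subjects = subjects, covariates = do.call(rbind, cov_rows),
         patterns = patterns, config = config),
    class = "cap_cohort"
  )
}

#' @export
print.cap_cohort <- function(x, ...) {
  tab <- table(vapply(x$subjects, `[[`, "", "group"))
  cat("<cap_cohort> ", length(x$subjects), " subjects (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), "), ",
      x$config$n_frames, " frames @ TR ", x$config$tr, " s, grid ",
      paste(x$config$grid, collapse = "x"), ", ", x$config$k_true,
      " planted states\n", sep = "")
  invisible(x)
}
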