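#' Run the full co-activation pattern pipeline on a cohort
#'
#' End-to-end orchestration: per-subject preprocessing (nuisance regression,
#' high-pass, scrubbing, z-scoring), seed-gated frame selection, pooling of
#' the control frames as the reference population, optional consensus-based
#' choice of K, k-means CAP extraction, assignment of every subject's frames
#' through the correlation-percentile threshold (by default the controls
#' too, so a small fraction of reference frames also ends up unassigned; set
#' `reassign_controls = FALSE` to let controls keep their clustering labels
#' instead), per-subject temporal metrics, and covariate-adjusted group
#' comparison with FDR control per metric family.
#'
#' @param cohort a `cap_cohort` (from [generate_cohort()]) or an equivalent
#'   list of subject bundles plus a covariates table.
#' @param seed a [seed_mask()]; default: the cohort's configured seed voxels.
#' @param k number of CAPs; `NULL` (default) selects K by consensus
#'   clustering over `k_range`.
#' @param k_range candidate K values for consensus selection (default 2:8).
#' @param select_mode,select_value frame selection mode and cut
#'   (default z threshold 0.84).
#' @param fd_threshold_mm,highpass_hz,head_radius_mm,use_global,smooth_fwhm
#'   preprocessing settings (see [preprocess()]).
#' @param n_subsamples,subsample_frac,pac_bounds consensus settings
#'   (see [consensus_cluster()]).
#' @param assign_percentile assignment-threshold percentile (default 0.05).
#' @param reassign_controls pass control frames through the assignment
#'   threshold like any other subject (default TRUE); `FALSE` keeps their
#'   k-means labels.
#' @param gap_mode transition gap handling, `"strict"` or `"collapse"`
#'   (see [transition_matrix()]).
#' @param nstart k-means restarts for the final clustering.
#' @param rng_seed integer seed controlling subsampling and k-means restarts.
#' @param compare run the group comparison stage (default TRUE).
#' @return Object of class `cap_pipeline`: `caps` (the fitted [cap_fit()]
#'   object), `consensus` (or NULL when K was given), `sequences`,
#'   `metrics` (per-subject [temporal_metrics()]), `metric_table`
#'   (subjects x metric columns), `covariates` (augmented with excluded- and
#'   selected-frame counts), `group_result`, `settings`.
#' @export
run_cap_pipeline <- function(cohort, seed = NULL, k = NULL, k_range = 2:8,
                             select_mode = "z_threshold", select_value = 0.84,
                             fd_threshold_mm = 0.5, highpass_hz = 0.01,
                             head_radius_mm = 50, use_global = TRUE,
                             smooth_fwhm = NULL,
                             n_subsamples = 100, subsample_frac = 0.8,
                             pac_bounds = c(0.1, 0.9),
                             assign_percentile = 0.05,
                             reassign_controls = TRUE,
                             gap_mode = "strict", nstart = 20,
                             rng_seed = 1L, compare = TRUE) {
  subjects <- cohort$subjects
  covs <- cohort$covariates
  n_sub <- length(subjects)
  if (is.null(seed)) {
    if (is.null(cohort$config$seed_voxels))
      stop("no seed mask given and the cohort carries no seed voxels")
    seed <- seed_mask_from_indices(cohort$config$seed_voxels,
                                   prod(cohort$config$grid))
  }
  pre <- vector("list", n_sub); sel <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    s <- subjects[[i]]
    pre[[i]] <- preprocess(s$series, s$motion, s$nuisance,
                           fd_threshold = fd_threshold_mm,
                           highpass_hz = highpass_hz,
                           head_radius_mm = head_radius_mm,
                           use_global = use_global,
                           smooth_fwhm = smooth_fwhm)
    sel[[i]] <- select_frames(pre[[i]], seed, mode = select_mode,
                              value = select_value, subject = s$id)
  }
  groups <- vapply(subjects, `[[`, "", "group")
  is_control <- groups == "control"
  pooled <- pool_frames(sel[is_control])
  consensus <- NULL
  if (is.null(k)) {
    consensus <- consensus_cluster(pooled$data, k_range = k_range,
                                   n_subsamples = n_subsamples,
                                   subsample_frac = subsample_frac,
                                   pac_bounds = pac_bounds,
                                   rng_seed = rng_seed,
                                   keep_consensus = FALSE)
    k <- consensus$chosen_k
  }
  caps <- cap_fit(pooled$data, k = k, nstart = nstart,
                  assign_percentile = assign_percentile, rng_seed = rng_seed)
  sequences <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    if (is_control[i] && !reassign_controls) {
      labs <- caps$labels[pooled$subject == subjects[[i]]$id]
    } else {
      labs <- predict(caps, sel[[i]]$data, use_threshold = TRUE)$labels
    }
    sequences[[i]] <- build_state_sequence(sel[[i]], labs, pre[[i]], k)
  }
  metrics <- lapply(sequences, temporal_metrics, gap_mode = gap_mode)
  mt <- metric_table(metrics, k)
  covs$n_excluded <- vapply(pre, `[[`, 0L, "n_excluded")
  covs$n_selected <- vapply(sel, `[[`, 0L, "n_selected")
  group_result <- NULL
  if (compare) {
    fam <- attr(mt, "family")
    group_result <- tryCatch(
      compare_groups(mt, covs, family = fam,
                     covariate_cols = intersect(
                       c("age", "sex", "medication", "bdi", "stai_s",
                         "n_excluded", "n_selected"), names(covs))),
      warning = function(w) {
        suppressWarnings(compare_groups(mt, covs, family = fam,
                                        covariate_cols = intersect(
                                          c("age", "sex", "medication", "bdi",
                                            "stai_s", "n_excluded",
                                            "n_selected"), names(covs))))
      })
  }
  structure(
    list(caps = caps, consensus = consensus, sequences = sequences,
         metrics = metrics, metric_table = mt, covariates = covs,
         group_result = group_result,
         settings = list(k = k, select_mode = select_mode,
                         select_value = select_value,
                         fd_threshold_mm = fd_threshold_mm,
                         highpass_hz = highpass_hz,
                         head_radius_mm = head_radius_mm,
                         use_global = use_global,
                         assign_percentile = assign_percentile,
                         reassign_controls = reassign_controls,
                         gap_mode = gap_mode,
                         n_subsamples = n_subsamples,
                         subsample_frac = subsample_frac,
                         pac_bounds = pac_bounds, nstart = nstart,
                         rng_seed = rng_seed)),
    class = "cap_pipeline"
  )
}

#' Flatten per-subject temporal metrics into a table
#'
#' One row per subject; columns `entries_k`, `duration_k`, `occupancy_k` for
#' each CAP and `T_m_n` for every transition cell, with a `family` attribute
#' naming the FDR family of each column.
#'
#' @param metrics list of [temporal_metrics()] objects.
#' @param k number of CAPs.
#' @return data.frame with attribute `family`.
#' @export
metric_table <- function(metrics, k) {
  rows <- lapply(metrics, function(m) {
    tm <- as.numeric(t(m$transition$T))      # row-major: T_1_1, T_1_2, ...
    c(m$entries, m$mean_duration, m$occupancy, tm)
  })
  mt <- as.data.frame(do.call(rbind, rows))
  names(mt) <- c(paste0("entries_", 1:k), paste0("duration_", 1:k),
                 paste0("occupancy_", 1:k),
                 paste0("T_", rep(1:k, each = k), "_", rep(1:k, k)))
  attr(mt, "family") <- c(rep("entries", k), rep("duration", k),
                          rep("occupancy", k), rep("transition", k * k))
  mt
}

#' @export
print.cap_pipeline <- function(x, ...) {
  cat("<cap_pipeline> K = ", x$settings$k, ", ",
      length(x$sequences), " subjects\n", sep = "")
  print(x$caps)
  if (!is.null(x$group_result)) {
    sig <- x$group_result[!is.na(x$group_result$p_fdr) &
                            x$group_result$p_fdr < 0.05, ]
    cat(nrow(sig), "metric(s) significant after FDR\n")
  }
  invisible(x)
}
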