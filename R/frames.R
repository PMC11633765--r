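#' Seed mask over the series' voxel columns
#'
#' Per-voxel weights in \[0, 1\]; probabilistic atlas values are used as-is
#' (weighted averaging preserves the atlas information for small nuclei),
#' binary masks are the 0/1 special case.
#'
#' @param weights numeric vector of per-voxel weights, aligned to the voxel
#'   columns of the series it will be applied to.
#' @return Object of class `seed_mask`.
#' @export
seed_mask <- function(weights) {
  weights <- as.numeric(weights)
  if (any(!is.finite(weights)) || any(weights < 0) || any(weights > 1))
    stop("seed weights must be finite and in [0, 1]")
  if (!any(weights > 0)) stop("seed mask has no positive weight")
  structure(list(weights = weights), class = "seed_mask")
}

# seed mask from voxel indices into a series' full-grid ordering
seed_mask_from_indices <- function(indices, n_vox) {
  w <- numeric(n_vox)
  w[indices] <- 1
  seed_mask(w)
}

#' Seed activation time course
#'
#' Weight-normalized mean of the (z-scored) voxel values inside the seed,
#' then z-scored over valid frames so a standard-normal threshold applies.
#'
#' @param series a preprocessed, z-scored [volume_series()].
#' @param seed a [seed_mask()] aligned to the series' voxel columns.
#' @return Numeric per-frame activation (z units over valid frames), with the
#'   pre-standardization weighted mean in attribute `"raw"`.
#' @export
seed_timecourse <- function(series, seed) {
  stopifnot(inherits(series, "volume_series"), inherits(seed, "seed_mask"))
  if (length(seed$weights) != n_voxels(series))
    stop("seed mask covers ", length(seed$weights),
         " voxels but series has ", n_voxels(series))
  w <- seed$weights / sum(seed$weights)
  raw <- as.numeric(series$data %*% w)
  v <- series$frame_valid
  z <- (raw - mean(raw[v])) / stats::sd(raw[v])
  attr(z, "raw") <- raw
  z
}

#' Standard-normal percentile threshold
#'
#' The z value such that a fraction `p` of a standard normal lies below it;
#' e.g. the 80th percentile is 0.84 SD, the usual cut for "high-amplitude"
#' seed events.
#'
#' @param p percentile in (0, 1).
#' @return The inverse standard-normal CDF at `p`.
#' @export
percentile_threshold <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
    stop("'p' must be a single value strictly between 0 and 1")
  stats::qnorm(p)
}

#' Select high-amplitude seed frames
#'
#' Keeps, among valid (non-censored) frames, those where the seed activation
#' is high: either above a z threshold on the standardized seed course
#' (default 0.84, the 80th standard-normal percentile) or the top fraction of
#' valid frames. The two coincide only under normality of the seed course,
#' which is why both are offered; the realized count is always recorded.
#'
#' @param series a preprocessed, z-scored [volume_series()].
#' @param seed a [seed_mask()].
#' @param mode `"z_threshold"` (default) or `"top_fraction"`.
#' @param value the z cut (default 0.84) or the fraction to keep.
#' @param subject optional subject identifier carried along.
#' @return Object of class `frame_set`: `subject`, `idx` (selected original
#'   frame indices, strictly increasing), `data` (selected frames x voxels),
#'   `n_selected`, `n_valid`, `seed_z` (full course).
#' @export
select_frames <- function(series, seed, mode = c("z_threshold", "top_fraction"),
                          value = 0.84, subject = NULL) {
  mode <- match.arg(mode)
  z <- seed_timecourse(series, seed)
  valid_idx <- which(series$frame_valid)
  if (mode == "z_threshold") {
    keep <- valid_idx[z[valid_idx] > value]
  } else {
    if (value <= 0 || value > 1) stop("'value' must be a fraction in (0, 1]")
    n_keep <- floor(value * length(valid_idx) + 1e-9)
    ord <- valid_idx[order(z[valid_idx], decreasing = TRUE)]
    keep <- sort(ord[seq_len(n_keep)])
  }
  if (length(keep) == 0L)
    warning("no frame survives seed-activation selection for subject ",
            if (is.null(subject)) "<unnamed>" else subject)
  structure(
    list(subject = subject, idx = keep,
         data = series$data[keep, , drop = FALSE],
         n_selected = length(keep), n_valid = length(valid_idx),
         seed_z = z),
    class = "frame_set"
  )
}

#' @export
print.frame_set <- function(x, ...) {
  cat("<frame_set> ", if (!is.null(x$subject)) paste0(x$subject, ": "),
      x$n_selected, " of ", x$n_valid, " valid frames selected\n", sep = "")
  invisible(x)
}

#' Pool frame sets into one reference matrix
#'
#' Stacks the selected frames of several subjects (typically the healthy
#' controls, which form the reference population for clustering).
#'
#' @param frame_sets list of [select_frames()] results.
#' @return List with `data` (pooled frames x voxels), `subject` (per row),
#'   `frame_idx` (original frame index per row).
#' @export
pool_frames <- function(frame_sets) {
  stopifnot(length(frame_sets) > 0L)
  data <- do.call(rbind, lapply(frame_sets, `[[`, "data"))
  subject <- unlist(lapply(frame_sets, function(f)
    rep(if (is.null(f$subject)) NA_character_ else f$subject, f$n_selected)))
  frame_idx <- unlist(lapply(frame_sets, `[[`, "idx"))
  list(data = data, subject = subject, frame_idx = frame_idx)
}
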