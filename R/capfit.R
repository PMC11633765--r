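#' Fit a set of co-activation patterns to reference frames
#'
#' The pipeline's central estimator. Runs k-means (Euclidean distance on the
#' z-scored frames, multiple restarts, best inertia kept) on the pooled
#' reference frames, builds one spatial map per cluster as the voxel-wise
#' mean of its member frames z-scored across voxels, and stores for each CAP
#' the distribution of member-frame-to-map spatial correlations together with
#' its lower percentile — the null used later to decide whether a held-out
#' frame matches any reference CAP at all. CAPs are re-indexed by descending
#' member count, so CAP 1 is always the most occupied pattern.
#'
#' @param x frames x voxels numeric matrix of selected, z-scored reference
#'   frames.
#' @param k number of CAPs (from [select_k()] or a user override).
#' @param nstart number of k-means restarts (default 20).
#' @param assign_percentile lower quantile of each CAP's member-correlation
#'   distribution used as its assignment threshold (default 0.05).
#' @param member_cor_method `"loo"` (default) computes each member frame's
#'   correlation against its CAP map rebuilt without that frame, so the
#'   stored distribution is not optimistically biased for frames outside the
#'   reference set; `"plain"` correlates against the full map.
#' @param rng_seed optional integer seed.
#' @param iter_max k-means iteration cap.
#' @return Object of class `cap_set` with components `maps` (voxels x K,
#'   z-scored across voxels), `labels` (reference-frame cluster memberships,
#'   re-indexed), `sizes`, `member_cor` (list of per-CAP correlation
#'   distributions), `thresholds` (per-CAP assignment cut), `k`, `inertia`.
#' @export
cap_fit <- function(x, k, nstart = 20, assign_percentile = 0.05,
                    member_cor_method = c("loo", "plain"),
                    rng_seed = NULL, iter_max = 100) {
  x <- as.matrix(x)
  k <- as.integer(k)
  member_cor_method <- match.arg(member_cor_method)
  if (k < 1L) stop("'k' must be >= 1")
  if (nrow(x) < k) stop("fewer frames (", nrow(x), ") than clusters (", k, ")")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  fit <- robust_kmeans(x, k, nstart = nstart, iter_max = iter_max)
  ord <- order(fit$size, decreasing = TRUE)
  labels <- match(fit$cluster, ord)
  maps <- vapply(seq_len(k), function(j) {
    m <- colMeans(x[labels == j, , drop = FALSE])
    as.numeric(scale(m))
  }, numeric(ncol(x)))
  member_cor <- lapply(seq_len(k), function(j) {
    mem <- which(labels == j)
    if (member_cor_method == "plain" || length(mem) < 3L)
      return(as.numeric(stats::cor(t(x[mem, , drop = FALSE]), maps[, j])))
    msum <- colSums(x[mem, , drop = FALSE])
    vapply(mem, function(i)
      stats::cor(x[i, ], (msum - x[i, ]) / (length(mem) - 1L)), numeric(1))
  })
  thresholds <- vapply(member_cor, stats::quantile,
                       numeric(1), probs = assign_percentile, names = FALSE)
  structure(
    list(maps = maps, labels = labels, sizes = fit$size[ord],
         member_cor = member_cor, thresholds = thresholds, k = k,
         assign_percentile = assign_percentile,
         inertia = fit$tot.withinss),
    class = "cap_set"
  )
}

#' @export
print.cap_set <- function(x, ...) {
  cat("<cap_set> ", x$k, " co-activation patterns over ", nrow(x$maps),
      " voxels (", sum(x$sizes), " reference frames)\n", sep = "")
  for (j in seq_len(x$k))
    cat(sprintf("  CAP%d: %d frames (%.1f%%), assignment r >= %.3f\n",
                j, x$sizes[j], 100 * x$sizes[j] / sum(x$sizes),
                x$thresholds[j]))
  invisible(x)
}

#' @export
summary.cap_set <- function(object, ...) {
  d <- data.frame(
    cap = seq_len(object$k),
    n_frames = object$sizes,
    occupancy = object$sizes / sum(object$sizes),
    median_r = vapply(object$member_cor, stats::median, numeric(1)),
    threshold_r = object$thresholds
  )
  class(d) <- c("summary.cap_set", "data.frame")
  d
}

#' @export
coef.cap_set <- function(object, ...) {
  m <- object$maps
  colnames(m) <- paste0("CAP", seq_len(object$k))
  m
}

#' Assign frames to reference co-activation patterns
#'
#' For each frame, computes the Pearson spatial correlation with every CAP
#' map; the candidate is the best-correlated CAP (ties to the lower index).
#' With thresholding on (the default), the frame is assigned only if its
#' correlation reaches that CAP's stored lower-percentile cut; otherwise it
#' is labeled unassigned — the mechanism that keeps frames unlike anything in
#' the reference population out of the dynamics. Zero-variance frames are
#' unassignable and flagged.
#'
#' @param object a [cap_fit()] result.
#' @param newdata frames x voxels matrix in the same voxel space as the maps.
#' @param use_threshold apply the percentile cut (default TRUE). `FALSE`
#'   reproduces plain nearest-map assignment (as used for the reference
#'   population itself, whose labels come from the clustering).
#' @param ... unused.
#' @return Object of class `cap_assignment`: `labels` (integer; 1..K, or
#'   `UNASSIGNED`), `best_cap`, `best_r`, `n_unassigned`,
#'   `zero_variance` flags.
#' @export
predict.cap_set <- function(object, newdata, use_threshold = TRUE, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$maps))
    stop("frame voxel count (", ncol(newdata),
         ") does not match CAP maps (", nrow(object$maps), ")")
  sds <- apply(newdata, 1, stats::sd)
  zero <- sds < 1e-12
  R <- matrix(NA_real_, nrow(newdata), object$k)
  if (any(!zero))
    R[!zero, ] <- stats::cor(t(newdata[!zero, , drop = FALSE]), object$maps)
  best <- apply(R, 1, function(r) if (all(is.na(r))) NA_integer_ else
    which.max(r))                      # which.max ties -> lowest index
  best_r <- R[cbind(seq_len(nrow(R)), best)]
  labels <- best
  if (use_threshold) {
    below <- !is.na(best) & best_r < object$thresholds[best]
    labels[below] <- UNASSIGNED
  }
  labels[zero] <- UNASSIGNED
  structure(
    list(labels = as.integer(labels), best_cap = as.integer(best),
         best_r = best_r, n_unassigned = sum(labels == UNASSIGNED),
         zero_variance = zero),
    class = "cap_assignment"
  )
}

#' @export
print.cap_assignment <- function(x, ...) {
  cat("<cap_assignment> ", length(x$labels), " frames, ",
      x$n_unassigned, " unassigned\n", sep = "")
  invisible(x)
}

#' Plot CAP maps as axial slices
#'
#' @param x a `cap_set`.
#' @param voxel_index,grid voxel geometry (as in [volume_series()]).
#' @param cap which CAP to draw (default 1).
#' @param ... passed to [graphics::image()].
#' @export
plot.cap_set <- function(x, voxel_index, grid, cap = 1, ...) {
  a <- frame_to_array(x$maps[, cap], voxel_index, grid)
  nz <- dim(a)[3]
  op <- graphics::par(mfrow = c(ceiling(nz / 4), min(nz, 4)),
                      mar = c(0.5, 0.5, 1.5, 0.5))
  on.exit(graphics::par(op))
  for (z in seq_len(nz))
    graphics::image(a[, , z], axes = FALSE,
                    main = sprintf("CAP%d z=%d", cap, z),
                    zlim = range(x$maps[, cap]), ...)
  invisible(x)
}
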