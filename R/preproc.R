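#' Framewise displacement (Power's criterion)
#'
#' Per-frame head-motion scalar: the sum of absolute frame-to-frame
#' differentials of the six realignment parameters, with rotations converted
#' to arc length on a sphere of radius `head_radius`. The first frame has no
#' predecessor and gets FD = 0.
#'
#' @param motion frames x 6 numeric matrix or data.frame, columns
#'   trans_x, trans_y, trans_z (mm), rot_x, rot_y, rot_z (radians).
#' @param head_radius sphere radius in mm for the rotation arc length
#'   (default 50, the usual convention).
#' @return Numeric vector of FD values in mm, one per frame.
#' @export
compute_fd <- function(motion, head_radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop("motion table must have 6 columns (3 translations, 3 rotations), got ",
         ncol(motion))
  if (nrow(motion) < 2L) stop("need at least 2 frames to compute FD")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Motion scrubbing
#'
#' Flags frames whose framewise displacement exceeds `threshold` as invalid.
#' Frames are never removed: censoring is recorded in `frame_valid` so later
#' stages can respect the original timeline. The count of newly censored
#' frames (the "excluded frames" covariate) is stored in `$n_excluded`.
#'
#' @param series a [volume_series()].
#' @param fd per-frame FD vector, as from [compute_fd()].
#' @param threshold censoring threshold in mm (default 0.5).
#' @return The series with updated `frame_valid` and `n_excluded`.
#' @export
scrub <- function(series, fd, threshold = 0.5) {
  stopifnot(inherits(series, "volume_series"))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("'threshold' must be positive (mm)")
  if (length(fd) != n_frames(series))
    stop("FD length (", length(fd), ") does not match frame count (",
         n_frames(series), ")")
  bad <- fd > threshold
  newly <- bad & series$frame_valid
  series$frame_valid[bad] <- FALSE
  series$n_excluded <- series$n_excluded + sum(newly)
  series$log <- c(series$log, sprintf("scrub(fd>%g): %d excluded",
                                      threshold, sum(newly)))
  series
}

#' Assemble a nuisance design matrix
#'
#' Columns: constant, linear and quadratic trends (orthogonal polynomials over
#' the timeline), optional white-matter and CSF mean courses, the six motion
#' parameters, and optionally the global (whole-mask mean) signal. Columns
#' that are numerically collinear with earlier columns are pruned with a
#' warning.
#'
#' @param n number of frames.
#' @param motion optional frames x 6 motion table.
#' @param wm,csf,global optional nuisance time courses (length n).
#' @param trends include constant/linear/quadratic trend columns
#'   (default TRUE).
#' @return Numeric matrix with labeled columns, full column rank.
#' @export
nuisance_design <- function(n, motion = NULL, wm = NULL, csf = NULL,
                            global = NULL, trends = TRUE) {
  cols <- list()
  if (trends) {
    tt <- seq_len(n)
    cols$constant <- rep(1, n)
    cols$trend_linear <- tt - mean(tt)
    cols$trend_quadratic <- (tt - mean(tt))^2
  }
  if (!is.null(wm)) cols$wm <- as.numeric(wm)
  if (!is.null(csf)) cols$csf <- as.numeric(csf)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (ncol(motion) != 6L) stop("motion table must have 6 columns")
    for (j in 1:6)
      cols[[c("trans_x", "trans_y", "trans_z",
              "rot_x", "rot_y", "rot_z")[j]]] <- motion[, j]
  }
  if (!is.null(global)) cols$global <- as.numeric(global)
  X <- do.call(cbind, cols)
  if (any(vapply(cols, length, 1L) != n))
    stop("all nuisance columns must have length ", n)
  prune_collinear(X)
}

# drop columns numerically dependent on earlier ones (pivoted QR)
prune_collinear <- function(X, tol = 1e-10, action = c("warn", "error")) {
  action <- match.arg(action)
  qrX <- qr(X, tol = tol)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    msg <- paste0("collinear column(s) dropped from design: ",
                  paste(drop, collapse = ", "))
    if (action == "error") stop(msg)
    warning(msg)
    X <- X[, setdiff(colnames(X), drop), drop = FALSE]
  }
  X
}

#' Regress out nuisance covariates
#'
#' Ordinary least squares per voxel: coefficients are estimated on valid
#' frames only, and the fitted nuisance component is subtracted from every
#' frame (censored frames are residualized too, but stay flagged).
#'
#' @param series a [volume_series()].
#' @param design frames x p design matrix, as from [nuisance_design()].
#' @return The residualized series.
#' @export
regress_nuisance <- function(series, design) {
  stopifnot(inherits(series, "volume_series"))
  design <- as.matrix(design)
  if (nrow(design) != n_frames(series))
    stop("design has ", nrow(design), " rows but series has ",
         n_frames(series), " frames")
  v <- series$frame_valid
  qrX <- qr(design[v, , drop = FALSE])
  if (qrX$rank < ncol(design)) {
    bad <- colnames(design)[qrX$pivot[(qrX$rank + 1L):ncol(design)]]
    stop("rank-deficient nuisance design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, series$data[v, , drop = FALSE])
  series$data <- series$data - design %*% beta
  series$log <- c(series$log, sprintf("regress(%d cols)", ncol(design)))
  series
}

#' High-pass filter via discrete-cosine basis projection
#'
#' Removes fluctuations slower than `cutoff` by regressing out the constant
#' term and the low-order discrete cosine transform basis functions whose
#' frequency k/(2*N*TR) lies below the cutoff — the standard drift model of
#' GLM-based fMRI pipelines, exactly linear and idempotent.
#'
#' @param series a [volume_series()].
#' @param cutoff high-pass cutoff in Hz (default 0.01).
#' @return The filtered series.
#' @export
highpass <- function(series, cutoff = 0.01) {
  stopifnot(inherits(series, "volume_series"))
  nyq <- 1 / (2 * series$tr)
  if (cutoff <= 0 || cutoff >= nyq)
    stop("cutoff must be in (0, Nyquist = ", signif(nyq, 4), " Hz)")
  N <- n_frames(series)
  K <- floor(2 * N * series$tr * cutoff)
  tt <- seq_len(N) - 0.5
  B <- vapply(0:K, function(k) cos(pi * tt * k / N), numeric(N))
  B <- qr.Q(qr(B))                      # orthonormal low-frequency basis
  series$data <- series$data - B %*% crossprod(B, series$data)
  series$log <- c(series$log, sprintf("highpass(%g Hz, %d dct)", cutoff, K))
  series
}

#' Spatial Gaussian smoothing
#'
#' Separable 3D Gaussian convolution on the voxel grid with mask-edge
#' renormalization (values outside the mask contribute nothing and the kernel
#' weight falling inside is rescaled to 1). FWHM is given in voxel units;
#' physical-space smoothing is a matter of voxel size, which the synthetic
#' grids do not model.
#'
#' @param series a [volume_series()].
#' @param fwhm full width at half maximum, in voxels.
#' @return The smoothed series.
#' @export
smooth_series <- function(series, fwhm) {
  stopifnot(inherits(series, "volume_series"))
  if (fwhm <= 0) stop("'fwhm' must be positive")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  kern <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  grid <- series$grid
  mask <- frame_to_array(rep(1, n_voxels(series)), series$voxel_index, grid)
  mask_sm <- conv3d_separable(mask, kern)
  for (t in seq_len(n_frames(series))) {
    a <- frame_to_array(series$data[t, ], series$voxel_index, grid)
    a <- conv3d_separable(a, kern) / pmax(mask_sm, .Machine$double.eps)
    series$data[t, ] <- a[series$voxel_index]
  }
  series$log <- c(series$log, sprintf("smooth(fwhm=%g vox)", fwhm))
  series
}

# separable convolution of a 3D array with a 1D kernel (zero padding)
conv3d_separable <- function(a, kern) {
  d <- dim(a)
  r <- (length(kern) - 1L) / 2L
  conv_axis <- function(m, n) {
    # m: n x (rest) matrix; convolve down columns
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(kern)) {
      off <- j - r - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + kern[j] * m[src[ok], , drop = FALSE]
    }
    out
  }
  a <- array(conv_axis(matrix(a, d[1]), d[1]), d)
  a <- aperm(a, c(2, 3, 1))
  a <- array(conv_axis(matrix(a, d[2]), d[2]), d[c(2, 3, 1)])
  a <- aperm(a, c(2, 3, 1))
  a <- array(conv_axis(matrix(a, d[3]), d[3]), d[c(3, 1, 2)])
  aperm(a, c(2, 3, 1))
}

#' Per-voxel z-scoring
#'
#' Centers and scales each voxel to mean 0, SD 1 over valid frames (sample SD,
#' n - 1 denominator); the same affine map is applied to censored frames so
#' they remain on a comparable scale. Zero-variance voxels are set to zero and
#' recorded in `$zero_variance_voxels`.
#'
#' @param series a [volume_series()].
#' @return The z-scored series.
#' @export
zscore_series <- function(series) {
  stopifnot(inherits(series, "volume_series"))
  v <- series$frame_valid
  if (sum(v) < 2L) stop("need at least 2 valid frames to z-score")
  mu <- colMeans(series$data[v, , drop = FALSE])
  sd <- apply(series$data[v, , drop = FALSE], 2, stats::sd)
  zero <- which(sd < 1e-12)
  sd[zero] <- 1
  series$data <- sweep(sweep(series$data, 2, mu), 2, sd, "/")
  series$data[, zero] <- 0
  series$zero_variance_voxels <- union(series$zero_variance_voxels, zero)
  series$log <- c(series$log, "zscore")
  series
}

#' Full preprocessing chain
#'
#' Fixed, logged order: nuisance regression, high-pass filtering, optional
#' spatial smoothing, motion scrubbing (flagging), per-voxel z-scoring.
#' Deterministic: re-running on identical input reproduces the output
#' bit-for-bit.
#'
#' @param series a [volume_series()].
#' @param motion frames x 6 motion-parameter table.
#' @param nuisance optional data.frame/list with `wm` and `csf` courses.
#' @param fd_threshold scrubbing threshold in mm (default 0.5).
#' @param highpass_hz high-pass cutoff (default 0.01); `NULL` to skip.
#' @param head_radius_mm FD rotation radius (default 50).
#' @param use_global include the global (mask-mean) signal as a nuisance
#'   regressor (default TRUE).
#' @param smooth_fwhm optional Gaussian FWHM in voxels; `NULL` to skip.
#' @return The preprocessed series (`n_excluded` holds the scrubbed-frame
#'   count).
#' @export
preprocess <- function(series, motion, nuisance = NULL, fd_threshold = 0.5,
                       highpass_hz = 0.01, head_radius_mm = 50,
                       use_global = TRUE, smooth_fwhm = NULL) {
  stopifnot(inherits(series, "volume_series"))
  gs <- if (use_global) rowMeans(series$data) else NULL
  X <- nuisance_design(n_frames(series), motion = motion,
                       wm = nuisance$wm, csf = nuisance$csf, global = gs)
  series <- regress_nuisance(series, X)
  if (!is.null(highpass_hz)) series <- highpass(series, highpass_hz)
  if (!is.null(smooth_fwhm)) series <- smooth_series(series, smooth_fwhm)
  fd <- compute_fd(motion, head_radius = head_radius_mm)
  series <- scrub(series, fd, threshold = fd_threshold)
  zscore_series(series)
}
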