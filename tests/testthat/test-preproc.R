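test_that("framewise displacement matches its definition", {
  zero <- matrix(0, 10, 6,
                 dimnames = list(NULL, c("trans_x", "trans_y", "trans_z",
                                         "rot_x", "rot_y", "rot_z")))
  expect_equal(compute_fd(zero), rep(0, 10))

  jump <- zero
  jump[5:10, 1:3] <- 0.2               # +0.2 mm step on each translation axis
  fd <- compute_fd(jump)
  expect_equal(fd[5], 0.6)
  expect_equal(fd[-5], rep(0, 9))

  # brute-force oracle: explicit per-frame loop over absolute differentials
  set.seed(42)
  m <- matrix(rnorm(60), 10, 6)
  oracle <- numeric(10)
  for (t in 2:10) {
    s <- 0
    for (j in 1:3) s <- s + abs(m[t, j] - m[t - 1, j])
    for (j in 4:6) s <- s + 50 * abs(m[t, j] - m[t - 1, j])
    oracle[t] <- s
  }
  expect_equal(compute_fd(m), oracle, tolerance = 1e-12)
  expect_error(compute_fd(m[, 1:5]), "6 columns")
})

test_that("scrubbing flags frames above threshold without deleting them", {
  ser <- toy_series(4)
  expect_equal(scrub(ser, rep(0, 4), 0.5)$n_excluded, 0L)
  s2 <- scrub(ser, c(0, 0.6, 0.4, 0.51), 0.5)
  expect_equal(which(!s2$frame_valid), c(2L, 4L))
  expect_equal(s2$n_excluded, 2L)
  expect_equal(nrow(s2$data), 4L)
  expect_error(scrub(ser, rep(0, 4), -1), "positive")

  # injected spikes: roughly binomial count of excluded frames
  excl <- vapply(1:6, function(r) {
    cfg <- sim_config(n_per_group = 1, motion_spike_prob = 0.1, rng_seed = r)
    coh <- generate_cohort(cfg)
    s <- coh$subjects[[1]]
    scrub(s$series, compute_fd(s$motion), 0.5)$n_excluded
  }, 1L)
  expect_gt(mean(excl), 15)            # ~30 expected at p = 0.1 over 300
  expect_lt(mean(excl), 45)
})

test_that("nuisance regression is an orthogonal projection per voxel", {
  ser <- toy_series(30)
  # constant-only design mean-centers each voxel
  out <- regress_nuisance(ser, cbind(constant = rep(1, 30)))
  expect_equal(colMeans(out$data), rep(0, ncol(out$data)), tolerance = 1e-12)

  set.seed(1)
  X <- nuisance_design(30, motion = matrix(rnorm(180), 30, 6),
                       wm = rnorm(30), csf = rnorm(30))
  # voxel lying in the design column space is annihilated
  ser2 <- ser
  ser2$data[, 1] <- X %*% runif(ncol(X))
  out2 <- regress_nuisance(ser2, X)
  expect_lt(max(abs(out2$data[, 1])), 1e-10)
  # residuals orthogonal to every design column
  for (j in seq_len(ncol(X)))
    expect_lt(max(abs(crossprod(X[, j], out2$data))), 1e-8)
  # duplicated column is named in the rank-deficiency error
  Xbad <- cbind(X, wm2 = X[, "wm"])
  expect_error(regress_nuisance(ser, Xbad), "wm2")
})

test_that("collinear design columns are pruned with a warning", {
  X <- cbind(a = rep(1, 20), b = seq_len(20), c = 2 * seq_len(20))
  expect_warning(Xp <- prune_collinear(X), "c")
  expect_equal(colnames(Xp), c("a", "b"))
})

test_that("DCT high-pass removes slow and keeps fast components", {
  n <- 300; tr <- 1.3
  tt <- (seq_len(n) - 1) * tr
  make <- function(f) toy_series(n, data = matrix(sin(2 * pi * f * tt),
                                                  n, 32), tr = tr)
  # amplitude measured as RMS ratio to the input tone
  slow <- highpass(make(0.002), 0.01)
  expect_lt(sd(slow$data[, 1]) / sd(sin(2 * pi * 0.002 * tt)), 0.05)
  fast <- highpass(make(0.1), 0.01)
  expect_gt(sd(fast$data[, 1]) / sd(sin(2 * pi * 0.1 * tt)), 0.95)
  const <- highpass(toy_series(n, data = matrix(7, n, 32), tr = tr), 0.01)
  expect_lt(max(abs(const$data)), 1e-10)
  expect_error(highpass(make(0.1), 1), "Nyquist")
})

test_that("z-scoring normalizes valid frames and flags flat voxels", {
  ser <- toy_series(40)
  ser$frame_valid[c(3, 10)] <- FALSE
  ser$data[, 2] <- 5                   # constant voxel
  z <- zscore_series(ser)
  v <- z$frame_valid
  expect_equal(colMeans(z$data[v, ]), rep(0, ncol(z$data)), tolerance = 1e-10)
  expect_equal(apply(z$data[v, -2], 2, sd), rep(1, ncol(z$data) - 1),
               tolerance = 1e-10)
  expect_true(all(z$data[, 2] == 0))
  expect_true(2L %in% z$zero_variance_voxels)

  # two-frame voxel: +/- 1/sqrt(2) under the n-1 SD convention
  s2 <- toy_series(2, data = matrix(c(1, 3), 2, 32))
  z2 <- zscore_series(s2)
  expect_equal(z2$data[, 1], c(-1, 1) / sqrt(2), tolerance = 1e-12)
})

test_that("spatial smoothing preserves means and is deterministic", {
  ser <- toy_series(5, grid = c(6, 6, 4))
  sm <- smooth_series(ser, fwhm = 2)
  expect_equal(dim(sm$data), dim(ser$data))
  # mask-renormalized convolution preserves a constant field exactly
  cs <- toy_series(2, grid = c(6, 6, 4), data = matrix(3, 2, 144))
  expect_equal(smooth_series(cs, 2)$data, cs$data, tolerance = 1e-12)
  expect_identical(smooth_series(ser, 2), smooth_series(ser, 2))
})

test_that("the preprocessing chain is deterministic and shape-preserving", {
  coh <- small_cohort(rng_seed = 17, n_per_group = 1)
  s <- coh$subjects[[1]]
  p1 <- preprocess(s$series, s$motion, s$nuisance)
  p2 <- preprocess(s$series, s$motion, s$nuisance)
  expect_identical(p1, p2)
  expect_equal(dim(p1$data), dim(s$series$data))
  expect_true(all(is.finite(p1$data)))
  expect_equal(p1$log[1], "regress(12 cols)")
})
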