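# three well-separated Gaussian blobs in feature space
blob_frames <- function(n_per = 20, nv = 40, sep = 6, sd = 0.5, seed = 1) {
  set.seed(seed)
  centers <- matrix(0, 3, nv)
  centers[1, 1:10] <- sep; centers[2, 11:20] <- sep; centers[3, 21:30] <- sep
  lab <- rep(1:3, each = n_per)
  list(x = centers[lab, ] + matrix(rnorm(3 * n_per * nv, sd = sd),
                                   3 * n_per, nv),
       labels = lab)
}

test_that("consensus matrices are block-diagonal for separated clusters", {
  b <- blob_frames()
  cc <- consensus_cluster(b$x, k_range = 3, n_subsamples = 40, nstart = 5,
                          rng_seed = 1, keep_consensus = TRUE)
  cons <- cc$consensus[[1]]
  expect_true(isSymmetric(cons))
  expect_equal(diag(cons), rep(1, nrow(cons)))
  expect_true(all(cons >= 0 & cons <= 1))
  same <- outer(b$labels, b$labels, "==")
  expect_gt(min(cons[same & cc$cosampled]), 0.95)
  expect_lt(max(cons[!same & cc$cosampled]), 0.05)
})

test_that("a single full-sample clustering gives a binary consensus", {
  b <- blob_frames(n_per = 10)
  cc <- consensus_cluster(b$x, k_range = 2:3, n_subsamples = 1,
                          subsample_frac = 1, rng_seed = 2)
  for (m in cc$consensus) expect_true(all(m %in% c(0, 1)))
})

test_that("consensus clustering reproduces exactly under a fixed seed", {
  b <- blob_frames()
  c1 <- consensus_cluster(b$x, k_range = 2:4, n_subsamples = 20, rng_seed = 9)
  c2 <- consensus_cluster(b$x, k_range = 2:4, n_subsamples = 20, rng_seed = 9)
  expect_identical(c1, c2)
  expect_error(consensus_cluster(b$x[1:5, ], k_range = 2:15), "exceeds")
})

test_that("PAC counts mid-range pairs and ignores never-co-sampled ones", {
  binary <- matrix(sample(c(0, 1), 64, replace = TRUE), 8, 8)
  binary <- (binary + t(binary)) / 2; binary[binary == 0.5] <- 1; diag(binary) <- 1
  expect_equal(pac(binary), 0)
  all_half <- matrix(0.5, 6, 6); diag(all_half) <- 1
  expect_equal(pac(all_half), 1)

  # brute-force O(n^2) pair-counting oracle on a random symmetric matrix
  set.seed(3)
  n <- 15
  m <- matrix(runif(n * n), n, n); m <- (m + t(m)) / 2; diag(m) <- 1
  co <- matrix(sample(c(TRUE, FALSE), n * n, TRUE, prob = c(.8, .2)), n, n)
  co <- co | t(co)
  num <- 0L; den <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (!co[i, j]) next
    den <- den + 1L
    if (m[i, j] > 0.1 && m[i, j] < 0.9) num <- num + 1L
  }
  expect_identical(pac(m, 0.1, 0.9, cosampled = co), num / den)
  # permutation invariance
  perm <- sample(n)
  expect_equal(pac(m[perm, perm], 0.1, 0.9, cosampled = co[perm, perm]),
               pac(m, 0.1, 0.9, cosampled = co))
  expect_error(pac(m, 0.9, 0.1), "u1 < u2")
})

test_that("K selection maximizes stability with ties toward smaller K", {
  b <- blob_frames()
  cc <- consensus_cluster(b$x, k_range = 2:5, n_subsamples = 40, rng_seed = 4)
  expect_equal(select_k(cc), 3L)
  tie <- cc
  tie$stability <- rep(0.5, length(tie$k_range))
  expect_warning(kt <- select_k(tie), "tie")
  expect_equal(kt, 2L)
})

test_that("planted 2-cluster data yields K = 2 across seeded replicates", {
  picks <- vapply(1:20, function(r) {
    set.seed(r)
    nv <- 30
    centers <- rbind(c(rep(5, 10), rep(0, 20)), c(rep(0, 20), rep(5, 10)))
    lab <- rep(1:2, each = 25)
    x <- centers[lab, ] + matrix(rnorm(50 * nv, sd = 0.7), 50, nv)
    consensus_cluster(x, k_range = 2:5, n_subsamples = 40,
                      rng_seed = 100 + r, keep_consensus = FALSE)$chosen_k
  }, 1L)
  expect_gte(sum(picks == 2L), 18)
})

test_that("cap_fit recovers planted maps and orders CAPs by occupancy", {
  cfg <- sim_config(rng_seed = 12)
  pats <- make_patterns(cfg)
  # noiseless frames with unequal state frequencies (0.39 / 0.37 / 0.24)
  lab <- rep(c(2L, 3L, 1L), times = c(39, 37, 24))
  x <- t(vapply(lab, function(s) pats[[s]], numeric(length(pats[[1]]))))
  fit <- cap_fit(x, k = 3, rng_seed = 1)
  expect_true(all(diff(fit$sizes) <= 0))
  expect_equal(fit$sizes, c(39L, 37L, 24L))
  # recovered maps match the z-scored planted patterns up to permutation
  zp <- vapply(pats, function(p) as.numeric(scale(p)), numeric(length(pats[[1]])))
  r <- abs(cor(fit$maps, zp))
  expect_equal(sort(apply(r, 1, max)), rep(1, 3), tolerance = 1e-3)
  # CAP1 is the most frequent planted state (state 2 above)
  expect_gt(abs(cor(fit$maps[, 1], zp[, 2])), 0.999)

  # K = 1: single map equals the z-scored grand mean frame
  f1 <- cap_fit(x, k = 1, rng_seed = 1)
  expect_equal(f1$maps[, 1], as.numeric(scale(colMeans(x))), tolerance = 1e-10)

  # fixed seed reproduces labels exactly
  set.seed(33)
  xn <- x + matrix(rnorm(length(x), sd = 0.5), nrow(x), ncol(x))
  expect_identical(cap_fit(xn, 3, rng_seed = 5)$labels,
                   cap_fit(xn, 3, rng_seed = 5)$labels)
})

test_that("member-correlation thresholds sit near the assignment percentile", {
  b <- blob_frames(n_per = 60, sd = 1)
  fit <- cap_fit(b$x, k = 3, rng_seed = 2)
  expect_true(all(fit$thresholds > -1 & fit$thresholds < 1))
  for (j in 1:3)
    expect_equal(stats::quantile(fit$member_cor[[j]], 0.05, names = FALSE),
                 fit$thresholds[j])
  # plain member correlations are optimistic relative to leave-one-out
  fit_plain <- cap_fit(b$x, k = 3, member_cor_method = "plain", rng_seed = 2)
  expect_true(all(fit_plain$thresholds >= fit$thresholds))
})
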