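fake_covs <- function(n_per = 14, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("s%02d", 1:(2 * n_per)),
    group = rep(c("control", "patient"), each = n_per),
    age = sample(20:58, 2 * n_per, replace = TRUE),
    sex = sample(c("F", "M"), 2 * n_per, replace = TRUE),
    medication = rbinom(2 * n_per, 1, 0.3),
    bdi = round(pmax(0, rnorm(2 * n_per, 8, 7))),
    stai_s = round(rnorm(2 * n_per, 35, 9)),
    stringsAsFactors = FALSE
  )
}

test_that("a pure group effect yields a large effect size", {
  cv <- fake_covs()
  metric <- as.numeric(cv$group == "patient")
  res <- adjust_and_compare(metric, cv)
  expect_gt(abs(res$d), 3)
  expect_lt(res$p, 0.001)
  expect_gt(res$diff, 0.99)            # patient - control sign convention
})

test_that("covariate adjustment removes a pure confound", {
  set.seed(4)
  reps <- t(replicate(200, {
    cv <- fake_covs(seed = sample.int(1e6, 1))
    # make age differ by group, metric driven only by age
    cv$age <- cv$age + ifelse(cv$group == "patient", 10, 0)
    metric <- 0.5 * cv$age + rnorm(nrow(cv), sd = 0.1)
    adj <- adjust_and_compare(metric, cv, covariate_cols = "age")$diff
    raw <- mean(metric[cv$group == "patient"]) -
      mean(metric[cv$group == "control"])
    c(adj = adj, raw = raw)
  }))
  expect_gt(mean(abs(reps[, "raw"])), 5 * mean(abs(reps[, "adj"])))
})

test_that("underpowered and degenerate inputs degrade gracefully", {
  cv <- fake_covs(n_per = 2)
  expect_warning(res <- adjust_and_compare(rnorm(4), cv), "fewer than 3")
  expect_true(is.na(res$p))
  cv2 <- fake_covs()
  cv2$dup <- cv2$age                    # collinear covariate gets pruned
  expect_warning(res2 <- adjust_and_compare(rnorm(28), cv2,
                                            covariate_cols = c("age", "dup")),
                 "collinear")
  expect_false(is.na(res2$p))
})

test_that("Benjamini-Hochberg adjustment matches hand-computed values", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_bh(0.2), 0.2)
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  set.seed(5)
  p <- runif(20)
  adj <- fdr_bh(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))   # monotone in p
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("Welch's t from summaries matches its closed form", {
  r <- welch_t_from_summary(38.1, 10.6, 14, 31.6, 6.65, 14)
  expect_equal(round(r$t, 2), 1.94)
  expect_equal(round(r$df, 2), 21.86, tolerance = 0.011)
  same <- welch_t_from_summary(5, 2, 10, 5, 2, 10)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # equal variances and n: df collapses to n1 + n2 - 2
  eq <- welch_t_from_summary(1, 3, 12, 2, 3, 12)
  expect_equal(eq$df, 22)
  # cross-check against t.test on raw data with matching summaries
  set.seed(6)
  x <- rnorm(14); y <- rnorm(14)
  ref <- t.test(x, y)
  mine <- welch_t_from_summary(mean(x), sd(x), 14, mean(y), sd(y), 14)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
})

test_that("Mann-Whitney Z handles ties, separation, and matches wilcox.test", {
  expect_equal(mann_whitney_z(c(1, 2, 3), c(1, 2, 3))$Z, 0)
  sep <- mann_whitney_z(1:14, 15:28)
  expect_equal(round(abs(sep$Z), 2), 4.48)
  expect_lt(sep$Z, 0)                   # group 1 smaller -> negative Z
  set.seed(7)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  mine <- mann_whitney_z(x, y)
  ref <- wilcox.test(x, y, correct = TRUE, exact = FALSE)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
})

test_that("Mann-Whitney normal approximation tracks the exact permutation law", {
  set.seed(8)
  x <- rnorm(8); y <- rnorm(8)
  obs <- mann_whitney_z(x, y)
  # exhaustive permutation oracle over all C(16, 8) group relabelings
  pooled <- c(x, y)
  combs <- utils::combn(16, 8)
  u_obs <- obs$U
  u_all <- apply(combs, 2, function(idx)
    sum(rank(pooled)[idx]) - 8 * 9 / 2)
  p_exact <- mean(abs(u_all - 32) >= abs(u_obs - 32))
  expect_lt(abs(obs$p - p_exact), 0.01)
})

test_that("seizure correlations use ranks and refuse tiny samples", {
  counts <- c(0, 1, 2, 5, 9, 20)
  r <- metric_seizure_correlation(log1p(counts) * 2 + 3, counts)
  expect_equal(r$rho, 1)
  expect_error(metric_seizure_correlation(1:3, 1:3), "insufficient n")
  flat <- metric_seizure_correlation(rep(1, 6), counts)
  expect_true(is.na(flat$rho))
  # null calibration: p values roughly uniform
  set.seed(9)
  ps <- replicate(500, metric_seizure_correlation(rnorm(14),
                                                  rpois(14, 5))$p)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("network overlap splits by sign and sums to 100 per side", {
  atlas <- rep(c("A", "B"), each = 50)
  m <- numeric(100)
  m[1:10] <- 2                          # positive only inside network A
  expect_warning(ov <- network_overlap(m, atlas, z_thresh = 1.04),
                 "negative side")
  expect_equal(unname(ov$positive["A"]), 100)
  expect_warning(expect_warning(network_overlap(m, atlas, z_thresh = 3),
                                "positive side"), "negative side")

  set.seed(10)
  z <- rnorm(20000)
  atlas2 <- rep(c("A", "B"), 10000)
  ov2 <- network_overlap(z, atlas2, z_thresh = 1.04)
  expect_equal(sum(ov2$positive), 100, tolerance = 1e-9)
  expect_equal(sum(ov2$negative), 100, tolerance = 1e-9)
  # ~15% of standard-normal voxels exceed +/- 1.04
  expect_equal(sum(z > 1.04) / 20000, 0.15, tolerance = 0.01)
  # uniform map over two equal networks splits about 50/50
  expect_equal(unname(ov2$positive["A"]), 50, tolerance = 3)
  # seed-voxel exclusion drops those voxels from the tally
  expect_warning(expect_warning(
    ov3 <- network_overlap(m, atlas, 1.04, exclude = 1:10),
    "positive side"), "negative side")
  expect_length(ov3$positive, 0)
})

test_that("compare_groups applies FDR within declared families", {
  cv <- fake_covs(seed = 11)
  set.seed(11)
  metrics <- data.frame(a = rnorm(28), b = rnorm(28),
                        c = as.numeric(cv$group == "patient") + rnorm(28, sd = 0.1))
  gr <- compare_groups(metrics, cv, family = c("f1", "f1", "f2"))
  expect_s3_class(gr, "group_result")
  expect_equal(gr$p_fdr[gr$family == "f1"], fdr_bh(gr$p[gr$family == "f1"]))
  expect_equal(gr$p_fdr[3], gr$p[3])    # single-member family unchanged
  expect_true(all(gr$p_fdr >= gr$p - 1e-15))
  expect_lt(gr$p_fdr[3], 0.001)
})
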