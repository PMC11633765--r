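#' Covariate-adjusted group comparison of one metric
#'
#' Linear model `metric ~ group + covariates` on complete cases; the group
#' coefficient (sign convention: patient minus control), its t statistic,
#' residual df and two-sided p are reported. Cohen's d is computed on
#' covariate-residualized values — residuals of `metric ~ covariates` (group
#' excluded) — standardized by the pooled SD, so the effect size matches the
#' adjusted contrast. Collinear covariate columns are pruned with a warning.
#'
#' @param metric numeric vector, one value per subject (`NA` allowed).
#' @param covariates data.frame with a `group` column (values `"control"` /
#'   `"patient"`) and the adjustment covariates.
#' @param covariate_cols names of the covariate columns to adjust for;
#'   default: all columns except `group` and `subject_id`.
#' @return One-row data.frame: `diff` (adjusted patient - control), `t`,
#'   `df`, `p`, `d` (Cohen), `n_control`, `n_patient`; all `NA` (with a
#'   warning) when fewer than 3 subjects per group have data.
#' @export
adjust_and_compare <- function(metric, covariates,
                               covariate_cols = NULL) {
  stopifnot(is.data.frame(covariates), "group" %in% names(covariates))
  if (is.null(covariate_cols))
    covariate_cols <- setdiff(names(covariates), c("group", "subject_id"))
  g <- factor(covariates$group, levels = c("control", "patient"))
  df0 <- data.frame(metric = as.numeric(metric), group = g,
                    covariates[covariate_cols], check.names = TRUE)
  cc <- stats::complete.cases(df0)
  df0 <- df0[cc, , drop = FALSE]
  n_con <- sum(df0$group == "control"); n_pat <- sum(df0$group == "patient")
  empty <- data.frame(diff = NA_real_, t = NA_real_, df = NA_real_,
                      p = NA_real_, d = NA_real_,
                      n_control = n_con, n_patient = n_pat)
  if (n_con < 3L || n_pat < 3L) {
    warning("fewer than 3 subjects per group with complete data; ",
            "comparison not performed")
    return(empty)
  }
  # prune covariates that are constant or collinear on the complete cases
  Xcov <- stats::model.matrix(~ ., df0[, setdiff(names(df0),
                                                 c("metric", "group")),
                                       drop = FALSE])
  Xcov <- tryCatch(prune_collinear(Xcov), warning = function(w) {
    warning(conditionMessage(w)); suppressWarnings(prune_collinear(Xcov))
  })
  X <- cbind(Xcov, group_patient = as.numeric(df0$group == "patient"))
  # drop columns that are collinear or exhaust the degrees of freedom,
  # never the group column itself
  qrX <- qr(X, tol = 1e-10)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    gi <- ncol(X)
    if (!(gi %in% keep)) {
      warning("group is collinear with the covariates; comparison not ",
              "identifiable")
      return(empty)
    }
    warning("covariate column(s) dropped to keep the model estimable: ",
            paste(colnames(X)[setdiff(seq_len(ncol(X)), keep)],
                  collapse = ", "))
    X <- X[, c(setdiff(keep, gi), gi), drop = FALSE]
    Xcov <- X[, -ncol(X), drop = FALSE]
  }
  if (nrow(X) - ncol(X) < 1L) {
    warning("no residual degrees of freedom; comparison not performed")
    return(empty)
  }
  fit <- stats::lm.fit(X, df0$metric)
  dfres <- length(df0$metric) - fit$rank
  sigma2 <- sum(fit$residuals^2) / dfres
  XtXinv <- chol2inv(chol(crossprod(X)))
  j <- ncol(X)
  se <- sqrt(sigma2 * XtXinv[j, j])
  est <- fit$coefficients[j]
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), dfres)
  # Cohen's d on covariate-residualized values, pooled SD
  res <- stats::lm.fit(Xcov, df0$metric)$residuals
  r_pat <- res[df0$group == "patient"]; r_con <- res[df0$group == "control"]
  sp <- sqrt(((n_pat - 1) * stats::var(r_pat) +
              (n_con - 1) * stats::var(r_con)) / (n_pat + n_con - 2))
  d <- if (sp > 0) (mean(r_pat) - mean(r_con)) / sp else NA_real_
  data.frame(diff = unname(est), t = unname(tval), df = dfres, p = unname(pval),
             d = d, n_control = n_con, n_patient = n_pat)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values (monotone, clipped at 1).
#'
#' @param p vector of raw p values in \[0, 1\].
#' @return Adjusted p values, same order as the input.
#' @export
fdr_bh <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Welch's t test from summary statistics
#'
#' Unequal-variance two-sample t with Welch-Satterthwaite degrees of freedom,
#' computable from printed group summaries (mean, SD, n) alone.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive")
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Mann-Whitney rank-sum Z
#'
#' The Z statistic is the tie-corrected normal approximation with continuity
#' correction (the quantity such studies print); positive Z means group 1
#' tends to exceed group 2. For small tie-free samples the p value comes from
#' the exact rank-sum null distribution — the usual convention, since the
#' normal approximation is coarse on a small lattice — and from the normal
#' approximation otherwise.
#'
#' @param x,y numeric samples (group 1, group 2).
#' @param continuity apply the 0.5 continuity correction (default TRUE).
#' @param exact use the exact null distribution for the p value; default
#'   `NULL` = automatic (exact when n1 + n2 <= 20 and there are no ties).
#' @return List with `Z`, `p` (two-sided), `U` (group-1 U statistic).
#' @export
mann_whitney_z <- function(x, y, continuity = TRUE, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("need at least one observation per group")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  N <- n1 + n2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(Z = 0, p = 1, U = U))
  dev <- U - mu
  if (continuity) dev <- sign(dev) * max(0, abs(dev) - 0.5)
  Z <- dev / sqrt(sigma2)
  if (is.null(exact)) exact <- N <= 20L && !has_ties
  if (exact && !has_ties) {
    d <- abs(U - mu)
    p <- min(1, stats::pwilcox(mu - d, n1, n2) +
               stats::pwilcox(mu + d - 1, n1, n2, lower.tail = FALSE))
  } else {
    p <- 2 * stats::pnorm(-abs(Z))
  }
  list(Z = Z, p = p, U = U)
}

#' Correlate temporal metrics with seizure counts
#'
#' Spearman rank correlation (appropriate for overdispersed count data)
#' between a per-patient metric and the recent seizure count.
#'
#' @param metric numeric vector, one value per patient.
#' @param counts seizure counts, same length.
#' @return List with `rho`, `p`, `n`.
#' @export
metric_seizure_correlation <- function(metric, counts) {
  ok <- stats::complete.cases(metric, counts)
  if (sum(ok) < 4L) stop("insufficient n: need >= 4 complete pairs")
  m <- metric[ok]; s <- counts[ok]
  if (stats::sd(m) == 0 || stats::sd(s) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = sum(ok)))
  ct <- suppressWarnings(stats::cor.test(m, s, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Network overlap of a thresholded CAP map
#'
#' Splits a z-scored spatial map at `+/- z_thresh` and reports, for each
#' sign, the percentage of suprathreshold voxels falling in each atlas label
#' (over labeled voxels; percentages per sign sum to 100). Seed voxels can be
#' excluded so the seed itself does not dominate its own map.
#'
#' @param cap_map numeric voxel vector (z-scored across voxels).
#' @param atlas integer/character label per voxel; 0 or `NA` = unlabeled.
#' @param z_thresh display threshold (default 1.04, i.e. the top ~15% of a
#'   standard normal per sign).
#' @param exclude optional voxel indices to drop (e.g. the seed).
#' @return List with `positive` and `negative`: named percentage vectors
#'   (possibly empty, with a warning, when no voxel survives).
#' @export
network_overlap <- function(cap_map, atlas, z_thresh = 1.04, exclude = NULL) {
  if (length(atlas) != length(cap_map))
    stop("atlas and map cover different voxel counts")
  keep <- rep(TRUE, length(cap_map))
  if (!is.null(exclude)) keep[exclude] <- FALSE
  labeled <- keep & !is.na(atlas) & atlas != 0
  side <- function(sel, name) {
    sel <- sel & labeled
    if (!any(sel)) {
      warning("no suprathreshold voxels on the ", name, " side")
      return(numeric(0))
    }
    tab <- table(atlas[sel])
    stats::setNames(100 * as.numeric(tab) / sum(tab), names(tab))
  }
  list(positive = side(cap_map > z_thresh, "positive"),
       negative = side(cap_map < -z_thresh, "negative"))
}

#' Compare temporal metrics between groups with FDR control
#'
#' Runs the covariate-adjusted comparison for every metric column and applies
#' Benjamini-Hochberg correction within each declared family (the transition
#' cells form one family; entries, durations and occupancies each their own),
#' mirroring how such metrics are reported separately.
#'
#' @param metrics data.frame of per-subject metric columns (rows aligned with
#'   `covariates`).
#' @param covariates data.frame with `group` and adjustment covariates.
#' @param family character vector, one family name per metric column;
#'   default: a single family.
#' @param covariate_cols passed to [adjust_and_compare()].
#' @return Object of class `group_result`: data.frame with one row per
#'   metric (`metric`, `family`, `diff`, `t`, `df`, `p`, `p_fdr`, `d`,
#'   `n_control`, `n_patient`). Sign convention: patient minus control.
#' @export
compare_groups <- function(metrics, covariates, family = NULL,
                           covariate_cols = NULL) {
  stopifnot(is.data.frame(metrics))
  if (is.null(family)) family <- rep("all", ncol(metrics))
  stopifnot(length(family) == ncol(metrics))
  rows <- lapply(seq_along(metrics), function(j)
    adjust_and_compare(metrics[[j]], covariates,
                       covariate_cols = covariate_cols))
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(metric = names(metrics), family = family,
                          stringsAsFactors = FALSE), out)
  out$p_fdr <- NA_real_
  for (f in unique(family)) {
    i <- which(out$family == f)
    out$p_fdr[i] <- fdr_bh(out$p[i])
  }
  rownames(out) <- NULL
  class(out) <- c("group_result", "data.frame")
  out
}

#' @export
print.group_result <- function(x, digits = 3, ...) {
  cat("Covariate-adjusted group comparison (patient - control)\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
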