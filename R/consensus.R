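#' Consensus clustering over a range of cluster counts
#'
#' For each candidate K, runs k-means on many random subsamples of the frames
#' and records, for every frame pair, how often the two were assigned to the
#' same cluster among the subsamples in which both were drawn. A stable K
#' yields a near-binary consensus matrix; instability shows up as mid-range
#' co-clustering frequencies, quantified by the proportion of ambiguously
#' clustered pairs (PAC).
#'
#' @param x frames x voxels numeric matrix (pooled reference frames).
#' @param k_range candidate cluster counts (default 2:15).
#' @param n_subsamples number of subsampled clusterings per K (default 100).
#' @param subsample_frac fraction of frames drawn per subsample
#'   (default 0.8).
#' @param pac_bounds ambiguity interval (u1, u2) for PAC (default
#'   c(0.1, 0.9)).
#' @param nstart k-means restarts per subsample run (default 1, the usual
#'   consensus-clustering convention: local optima are part of the
#'   instability the method measures).
#' @param rng_seed optional integer seed for reproducibility.
#' @param iter_max k-means iteration cap per run.
#' @param keep_consensus store the full consensus matrices (default TRUE;
#'   set FALSE to save memory when only the PAC curve is needed).
#' @return Object of class `cap_consensus`: `k_range`, `pac`, `stability`
#'   (1 - PAC), `chosen_k`, and (optionally) `consensus`, a list of
#'   symmetric unit-diagonal matrices with entries in \[0, 1\] plus a
#'   `cosampled` logical matrix marking pairs ever drawn together.
#' @export
consensus_cluster <- function(x, k_range = 2:15, n_subsamples = 100,
                              subsample_frac = 0.8, pac_bounds = c(0.1, 0.9),
                              rng_seed = NULL, nstart = 1, iter_max = 50,
                              keep_consensus = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > n)
    stop("k_range maximum (", max(k_range), ") exceeds frame count (", n, ")")
  if (n < max(k_range) * 5L)
    warning("fewer than 5 frames per candidate cluster; consensus may be unstable")
  if (subsample_frac <= 0 || subsample_frac > 1)
    stop("'subsample_frac' must be in (0, 1]")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  m <- max(2L, round(subsample_frac * n))
  # draw the subsamples once so every K sees the same ones
  subs <- lapply(seq_len(n_subsamples), function(b) sort(sample.int(n, m)))
  I <- matrix(0L, n, n)
  for (s in subs) I[s, s] <- I[s, s] + 1L
  pac_values <- numeric(length(k_range))
  cons_list <- if (keep_consensus) vector("list", length(k_range)) else NULL
  for (ki in seq_along(k_range)) {
    K <- k_range[ki]
    M <- matrix(0L, n, n)
    for (s in subs) {
      lab <- robust_kmeans(x[s, , drop = FALSE], K, nstart = nstart,
                           iter_max = iter_max)$cluster
      M[s, s] <- M[s, s] + (outer(lab, lab, "==") * 1L)
    }
    cons <- matrix(0, n, n)
    co <- I > 0L
    cons[co] <- M[co] / I[co]
    diag(cons) <- 1
    pac_values[ki] <- pac(cons, pac_bounds[1], pac_bounds[2], cosampled = co)
    if (keep_consensus) cons_list[[ki]] <- cons
  }
  names(pac_values) <- paste0("K", k_range)
  res <- structure(
    list(k_range = k_range, pac = pac_values, stability = 1 - pac_values,
         consensus = cons_list, cosampled = if (keep_consensus) I > 0L else NULL,
         n_subsamples = n_subsamples, subsample_frac = subsample_frac,
         pac_bounds = pac_bounds, n = n),
    class = "cap_consensus"
  )
  res$chosen_k <- select_k(res, quiet = TRUE)
  res
}

# kmeans with retries on empty-cluster / convergence failures
robust_kmeans <- function(x, k, nstart = 1, iter_max = 50, max_attempts = 10) {
  for (a in seq_len(max_attempts)) {
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = k, nstart = nstart,
                                     iter.max = iter_max)),
      error = function(e) NULL)
    if (!is.null(fit) && all(fit$size > 0L)) return(fit)
  }
  stop("k-means failed to produce ", k, " non-empty clusters after ",
       max_attempts, " attempts")
}

#' Proportion of ambiguously clustered pairs
#'
#' The fraction of off-diagonal, co-sampled frame pairs whose consensus value
#' lies strictly inside the ambiguity interval (u1, u2). Lower is more
#' stable; 1 - PAC is the stability score used for model selection.
#'
#' @param consensus symmetric consensus matrix with entries in \[0, 1\].
#' @param u1,u2 ambiguity bounds, 0 <= u1 < u2 <= 1 (defaults 0.1, 0.9).
#' @param cosampled optional logical matrix marking pairs that were drawn
#'   together at least once; pairs never co-sampled are excluded. Default:
#'   all pairs counted.
#' @return PAC in \[0, 1\].
#' @export
pac <- function(consensus, u1 = 0.1, u2 = 0.9, cosampled = NULL) {
  if (!(u1 >= 0 && u1 < u2 && u2 <= 1))
    stop("need 0 <= u1 < u2 <= 1")
  consensus <- as.matrix(consensus)
  keep <- upper.tri(consensus)
  if (!is.null(cosampled)) keep <- keep & cosampled
  vals <- consensus[keep]
  if (length(vals) == 0L) return(NA_real_)
  mean(vals > u1 & vals < u2)
}

#' Select the number of clusters from a consensus result
#'
#' Picks the K with maximal stability (1 - PAC); ties break toward the
#' smaller K, with a warning. The full PAC-versus-K table remains available
#' on the `cap_consensus` object for inspection of the consensus matrices.
#'
#' @param result a [consensus_cluster()] result.
#' @param quiet suppress the tie warning.
#' @return The selected K (integer).
#' @export
select_k <- function(result, quiet = FALSE) {
  stopifnot(inherits(result, "cap_consensus"))
  stab <- result$stability
  best <- which(stab == max(stab))
  if (length(best) > 1L && !quiet)
    warning("stability tie between K = ",
            paste(result$k_range[best], collapse = ", "),
            "; returning the smallest")
  result$k_range[min(best)]
}

#' @export
print.cap_consensus <- function(x, ...) {
  cat("<cap_consensus> ", x$n, " frames, K scanned ",
      min(x$k_range), "..", max(x$k_range), " (", x$n_subsamples,
      " subsamples at ", 100 * x$subsample_frac, "%)\n", sep = "")
  tab <- data.frame(K = x$k_range, PAC = round(x$pac, 4),
                    stability = round(x$stability, 4))
  print(tab, row.names = FALSE)
  cat("selected K = ", x$chosen_k, "\n", sep = "")
  invisible(x)
}

#' @export
plot.cap_consensus <- function(x, ...) {
  graphics::plot(x$k_range, x$stability, type = "b", pch = 19,
                 xlab = "K", ylab = "stability (1 - PAC)", ...)
  graphics::abline(v = x$chosen_k, lty = 2, col = "grey40")
  invisible(x)
}
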