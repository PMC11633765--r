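#' Frame-state codes
#'
#' A state sequence assigns each original acquisition frame one label:
#' a CAP index (positive integer), `NOT_SELECTED` (valid frame whose seed
#' activation was below the selection cut), `UNASSIGNED` (selected frame
#' matching no reference CAP), or `CENSORED` (motion-scrubbed frame).
#'
#' @name state_codes
#' @export
NOT_SELECTED <- 0L

#' @rdname state_codes
#' @export
UNASSIGNED <- -1L

#' @rdname state_codes
#' @export
CENSORED <- -2L

#' Per-subject state sequence
#'
#' One label per original acquisition timepoint, preserving the scan's
#' temporal adjacency. Everything temporal (entries, durations, occupancy,
#' transitions) derives from this object.
#'
#' @param labels integer vector over the original timeline: CAP indices
#'   1..k, or [NOT_SELECTED], [UNASSIGNED], [CENSORED].
#' @param k number of CAPs.
#' @param tr repetition time in seconds.
#' @param subject optional subject id.
#' @return Object of class `state_sequence`.
#' @export
state_sequence <- function(labels, k, tr, subject = NULL) {
  labels <- as.integer(labels)
  k <- as.integer(k)
  if (any(is.na(labels)) || any(labels < CENSORED) || any(labels > k))
    stop("labels must be in {", CENSORED, "..", k, "} with no NA")
  structure(list(labels = labels, k = k, tr = tr, subject = subject),
            class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  cat("<state_sequence> ", if (!is.null(x$subject)) paste0(x$subject, ": "),
      length(x$labels), " frames, ", x$k, " CAPs; assigned ",
      sum(x$labels > 0L), ", not-selected ", sum(x$labels == NOT_SELECTED),
      ", unassigned ", sum(x$labels == UNASSIGNED),
      ", censored ", sum(x$labels == CENSORED), "\n", sep = "")
  invisible(x)
}

#' Compose a full-timeline state sequence
#'
#' Merges censoring flags, the frame selection, and the CAP assignment of the
#' selected frames into one per-timepoint label vector.
#'
#' @param frame_set a [select_frames()] result.
#' @param assignment a [predict.cap_set()] result (or an integer label vector)
#'   for exactly the selected frames.
#' @param series the subject's preprocessed [volume_series()] (supplies frame
#'   count, validity flags and TR).
#' @param k number of CAPs.
#' @return A [state_sequence()].
#' @export
build_state_sequence <- function(frame_set, assignment, series, k) {
  stopifnot(inherits(frame_set, "frame_set"),
            inherits(series, "volume_series"))
  labs <- if (inherits(assignment, "cap_assignment")) assignment$labels
          else as.integer(assignment)
  if (length(labs) != frame_set$n_selected)
    stop("assignment covers ", length(labs), " frames but ",
         frame_set$n_selected, " were selected")
  full <- rep(NOT_SELECTED, n_frames(series))
  full[!series$frame_valid] <- CENSORED
  full[frame_set$idx] <- labs
  state_sequence(full, k = k, tr = series$tr, subject = frame_set$subject)
}

# runs of a given CAP label; any other label (including gaps) breaks a run
cap_runs <- function(seq, k) {
  r <- rle(seq$labels)
  r$lengths[r$values == k]
}

#' Number of entries into a CAP
#'
#' Counts maximal runs of consecutive frames labeled `k`; a run is broken by
#' any other label, including censored and not-selected frames.
#'
#' @param seq a [state_sequence()].
#' @param k CAP index.
#' @return Integer count.
#' @export
entries <- function(seq, k) {
  stopifnot(inherits(seq, "state_sequence"))
  length(cap_runs(seq, k))
}

#' Mean dwell duration of a CAP, in seconds
#'
#' Average run length (frames) multiplied by the repetition time. If the CAP
#' never occurs the duration is undefined and returned as `NA` (never zero,
#' which would fake an observation).
#'
#' @param seq a [state_sequence()].
#' @param k CAP index.
#' @return Seconds, or `NA_real_` if the CAP has no run.
#' @export
mean_duration <- function(seq, k) {
  stopifnot(inherits(seq, "state_sequence"))
  runs <- cap_runs(seq, k)
  if (length(runs) == 0L) return(NA_real_)
  mean(runs) * seq$tr
}

#' Per-CAP occupancy
#'
#' Fraction of assigned frames spent in each CAP; the fractions sum to 1.
#'
#' @param seq a [state_sequence()].
#' @return Numeric vector of length k, or all-`NA` with a warning when no
#'   frame is assigned.
#' @export
occupancy <- function(seq) {
  stopifnot(inherits(seq, "state_sequence"))
  assigned <- seq$labels[seq$labels > 0L]
  if (length(assigned) == 0L) {
    warning("no assigned frames; occupancy undefined")
    return(rep(NA_real_, seq$k))
  }
  tabulate(assigned, nbins = seq$k) / length(assigned)
}

#' Empirical CAP transition matrix
#'
#' Counts ordered pairs of originally adjacent timepoints (t, t+1) where both
#' frames carry CAP labels; pairs touching a censored, not-selected or
#' unassigned frame contribute nothing (gaps are gaps, not transitions).
#' Row m of `T` is the conditional distribution of the next CAP given CAP m;
#' rows with zero observed pairs are undefined (`NA`) and flagged, not zero.
#'
#' Under `gap_mode = "strict"` (the default, the literal reading of
#' "timepoint t to timepoint t + 1") only originally adjacent CAP-CAP pairs
#' count. Under `"collapse"` all gap labels are dropped first and successive
#' CAP frames are paired across gaps — a coarser estimator that is far more
#' sensitive to state persistence, since run endings that pass through
#' unselected frames still contribute a pair.
#'
#' @param seq a [state_sequence()].
#' @param gap_mode `"strict"` or `"collapse"`.
#' @return List with `T` (k x k, rows summing to 1 or all-`NA`), `counts`
#'   (k x k integer), `missing_rows` (logical per row).
#' @export
transition_matrix <- function(seq, gap_mode = c("strict", "collapse")) {
  stopifnot(inherits(seq, "state_sequence"))
  gap_mode <- match.arg(gap_mode)
  k <- seq$k
  labs <- if (gap_mode == "collapse") seq$labels[seq$labels > 0L] else
    seq$labels
  if (length(labs) < 2L) {
    counts <- matrix(0L, k, k)
    dimnames(counts) <- list(from = paste0("CAP", 1:k),
                             to = paste0("CAP", 1:k))
    return(list(T = counts * NA_real_, counts = counts,
                missing_rows = rep(TRUE, k)))
  }
  a <- labs[-length(labs)]
  b <- labs[-1L]
  keep <- a > 0L & b > 0L
  counts <- matrix(0L, k, k)
  if (any(keep)) {
    tab <- tabulate((a[keep] - 1L) * k + b[keep], nbins = k * k)
    counts <- matrix(tab, k, k, byrow = TRUE)
  }
  rs <- rowSums(counts)
  Tm <- counts / ifelse(rs > 0L, rs, NA_real_)
  dimnames(Tm) <- dimnames(counts) <-
    list(from = paste0("CAP", 1:k), to = paste0("CAP", 1:k))
  list(T = Tm, counts = counts, missing_rows = rs == 0L)
}

#' Per-subject temporal metrics
#'
#' Entries, mean durations, occupancy and the transition matrix of one
#' subject's state sequence.
#'
#' @param seq a [state_sequence()].
#' @param gap_mode gap handling for the transition matrix (see
#'   [transition_matrix()]).
#' @return Object of class `temporal_metrics`: `subject`, `entries`,
#'   `mean_duration` (seconds), `occupancy`, `transition` (list as from
#'   [transition_matrix()]), `n_assigned`.
#' @export
temporal_metrics <- function(seq, gap_mode = "strict") {
  stopifnot(inherits(seq, "state_sequence"))
  k <- seq$k
  occ <- suppressWarnings(occupancy(seq))
  structure(
    list(subject = seq$subject,
         entries = vapply(seq_len(k), function(j) entries(seq, j), 1L),
         mean_duration = vapply(seq_len(k), function(j) mean_duration(seq, j),
                                1.0),
         occupancy = occ,
         transition = transition_matrix(seq, gap_mode = gap_mode),
         n_assigned = sum(seq$labels > 0L)),
    class = "temporal_metrics"
  )
}

#' @export
print.temporal_metrics <- function(x, ...) {
  k <- length(x$entries)
  cat("<temporal_metrics>", if (!is.null(x$subject)) x$subject, "\n")
  d <- data.frame(cap = seq_len(k), entries = x$entries,
                  duration_s = round(x$mean_duration, 3),
                  occupancy = round(x$occupancy, 3))
  print(d, row.names = FALSE)
  cat("transition matrix:\n")
  print(round(x$transition$T, 3))
  invisible(x)
}
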