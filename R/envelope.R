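# Movement observables: a rectified, smoothed amplitude envelope and the
# robust threshold detector that turns envelope excursions into discrete
# movement events.

#' Movement amplitude envelope of a recording
#'
#' Sliding root-mean-square of the (filtered) trace over a short centered
#' window: a non-negative series on the same time base as the recording,
#' tracking "large-scale movement-related excursions" while averaging over
#' individual oscillation cycles.
#'
#' @param rec An `ef_recording` (non-empty).
#' @param smoothing_window_s RMS window length in seconds (default 0.25 s,
#'   about one breathing cycle).
#' @return An `envelope_series`: list with `values`, `rate`,
#'   `smoothing_window_s`.
#' @export
movement_envelope <- function(rec, smoothing_window_s = 0.25) {
  stopifnot(inherits(rec, "ef_recording"))
  if (length(rec$samples) == 0) stop("empty recording")
  w <- max(1L, round(smoothing_window_s * rec$sampling_rate))
  structure(
    list(values = sliding_rms_cpp(rec$samples, w),
         rate = rec$sampling_rate,
         smoothing_window_s = smoothing_window_s),
    class = "envelope_series")
}

#' Detect movement events in an amplitude envelope
#'
#' Robust, amplitude-scale-free thresholding. The quiescent baseline is
#' estimated from the lowest-decile 1 s segments of the envelope (by segment
#' mean); the detection threshold is `median + threshold_k * MAD` of the
#' pooled baseline samples. Events are maximal runs above the threshold,
#' extended by hysteresis down to `median + threshold_k/2 * MAD` (half the
#' excursion above baseline); runs separated by less than `merge_gap_s` are
#' merged, runs shorter than `min_duration_s` discarded. Events are returned
#' `UNCLASSIFIED`; see [classify_events()].
#'
#' If the baseline MAD is zero (degenerate constant envelope) the detector
#' falls back to the absolute threshold `fallback_threshold` and emits a
#' warning.
#'
#' @param env An `envelope_series`.
#' @param threshold_k MAD multiplier (default 5).
#' @param merge_gap_s Merge events closer than this gap in seconds.
#' @param min_duration_s Discard events shorter than this, in seconds.
#' @param fallback_threshold Absolute threshold in volts used when MAD = 0.
#' @return `data.frame` with columns `start_s`, `end_s`, `duration_s`,
#'   `peak_amplitude`, `event_class`.
#' @export
detect_movement_events <- function(env, threshold_k = 5, merge_gap_s = 0.2,
                                   min_duration_s = 0.05,
                                   fallback_threshold = 0.5) {
  stopifnot(inherits(env, "envelope_series"))
  v <- env$values
  if (!length(v)) stop("empty envelope")
  bl <- .baseline_samples(v, env$rate)
  med <- stats::median(bl)
  dev <- stats::mad(bl)
  if (dev == 0) {
    warning("baseline MAD is zero; falling back to absolute threshold")
    upper <- fallback_threshold
    lower <- fallback_threshold / 2
  } else {
    upper <- med + threshold_k * dev
    lower <- med + threshold_k / 2 * dev
  }
  ev <- .threshold_events(v, env$rate, upper, lower, merge_gap_s, min_duration_s)
  ev$event_class <- rep("UNCLASSIFIED", nrow(ev))
  ev
}

# Pool the envelope samples belonging to the lowest-decile 1 s segments.
.baseline_samples <- function(v, rate) {
  seg <- max(1L, round(rate)) # 1 s segments
  ns <- length(v) %/% seg
  if (ns < 2) return(v)
  means <- colMeans(matrix(v[seq_len(ns * seg)], nrow = seg))
  cut <- stats::quantile(means, 0.1, names = FALSE)
  keep <- which(means <= cut)
  idx <- rep((keep - 1L) * seg, each = seg) + rep(seq_len(seg), times = length(keep))
  v[idx]
}

# Vectorized run extraction: runs above `lower` that touch `upper` at least
# once, then gap merging and minimum-duration pruning.
.threshold_events <- function(v, rate, upper, lower, merge_gap_s, min_duration_s) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), peak_amplitude = numeric(0))
  r <- rle(v > lower)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values)
  if (!length(cand)) return(empty)
  keep <- vapply(cand, function(i) any(v[starts[i]:ends[i]] > upper), logical(1))
  cand <- cand[keep]
  if (!length(cand)) return(empty)
  s <- starts[cand]
  e <- ends[cand]
  # merge runs separated by less than merge_gap_s
  if (length(s) > 1) {
    gap <- (s[-1] - e[-length(e)] - 1) / rate
    new_run <- c(TRUE, gap >= merge_gap_s)
    gid <- cumsum(new_run)
    s <- tapply(s, gid, min)
    e <- tapply(e, gid, max)
  }
  start_s <- (s - 1) / rate
  end_s <- e / rate
  dur <- end_s - start_s
  ok <- dur >= min_duration_s
  s <- s[ok]; e <- e[ok]
  start_s <- start_s[ok]; end_s <- end_s[ok]
  if (!length(s)) return(empty)
  peak <- mapply(function(i, j) max(v[i:j]), s, e)
  data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
             duration_s = as.numeric(end_s - start_s),
             peak_amplitude = as.numeric(peak), row.names = NULL)
}
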