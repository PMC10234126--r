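# Raw-trace conditioning: the acquisition chain low-passes EF signals at
# 30 Hz before analysis. The digital equivalent here is a zero-phase
# (forward-backward) 4th-order Butterworth, so movement-event boundaries are
# not skewed by filter delay.

#' Zero-phase low-pass filter an EF recording
#'
#' 4th-order Butterworth (coefficients from [signal::butter()]) applied
#' forward and backward with odd-reflection edge padding, giving zero phase
#' and an effective 8th-order magnitude response. Output length equals input
#' length.
#'
#' @param rec An `ef_recording`.
#' @param cutoff Cutoff frequency in Hz (default 30, the acquisition value).
#' @param order Butterworth order per pass.
#' @return A filtered `ef_recording`.
#' @export
lowpass_filter <- function(rec, cutoff = 30, order = 4) {
  stopifnot(inherits(rec, "ef_recording"))
  fs <- rec$sampling_rate
  if (cutoff >= fs / 2) {
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency (",
         fs / 2, " Hz)")
  }
  n <- length(rec$samples)
  if (n == 0) return(rec)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  b <- bf$b / bf$a[1]
  a <- bf$a / bf$a[1]
  # odd-reflection padding long enough for the startup transient to die out
  p <- min(n - 1, ceiling(10 * fs / cutoff))
  x <- rec$samples
  if (p > 0) {
    xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  } else {
    xp <- x
  }
  # removing the first value before filtering and adding it back exploits
  # the unit DC gain of the low-pass, so constant signals pass through
  # exactly despite the zero initial filter state
  x0 <- xp[1]
  y <- filtfilt_cpp(b, a, xp - x0) + x0
  if (p > 0) y <- y[(p + 1):(p + n)]
  out <- rec
  out$samples <- pmin(5, pmax(-5, y))
  out
}
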