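# Spectrogram ("sonogram") summaries of EF recordings. Display settings
# follow the acquisition-software convention used for these recordings:
# block size 4096 samples, Hann window, top dB 38, range dB 33, frequency
# axis truncated at 30 Hz. The top/range pair defines a display window onto
# relative power: the session's loudest block-bin is drawn at `top_db` and
# anything more than `range_db` below it clips to the floor. Linear power
# (normalized so a full-scale 5 V sine is 1) is kept alongside the clipped
# display matrix for quantitative summaries.

#' Compute an EF spectrogram
#'
#' Short-time power spectrum via [signal::specgram()] with a Hann window and
#' 50% block overlap. `power` is linear, normalized so a full-scale 5 V
#' sine at a bin center gives 1. `power_db` is the display matrix: dB
#' relative to the maximum observed block-bin power, shifted so that
#' maximum sits at `top_db`, then clipped to `[top_db - range_db, top_db]`;
#' the frequency axis is truncated at 30 Hz.
#'
#' @param rec An `ef_recording`.
#' @param block Block size in samples (default 4096; must not exceed the
#'   record length).
#' @param window Window name; only `"hanning"` is supported.
#' @param top_db,range_db Display clipping bounds in dB.
#' @param max_freq Upper frequency bound of the returned axis, Hz.
#' @return A `spectrogram_result`: list with `times`, `freqs`, `power`
#'   (linear, time x freq), `power_db` (clipped, time x freq), `block_size`,
#'   `window_name`, `top_db`, `range_db`.
#' @export
compute_spectrogram <- function(rec, block = 4096, window = "hanning",
                                top_db = 38, range_db = 33, max_freq = 30) {
  stopifnot(inherits(rec, "ef_recording"))
  n <- length(rec$samples)
  if (block > n) stop("block size (", block, ") exceeds record length (", n, ")")
  if (!identical(window, "hanning")) stop("only the hanning window is supported")
  win <- signal::hanning(block)
  sg <- signal::specgram(rec$samples, n = block, Fs = rec$sampling_rate,
                         window = win, overlap = block / 2)
  # one-sided amplitude estimate: a full-scale 5 V sine at a bin center
  # gives amplitude 5, i.e. 0 dB re full scale
  amp <- 2 * Mod(sg$S) / sum(win)
  keep <- sg$f <= max_freq
  power <- t((amp[keep, , drop = FALSE] / 5)^2) # time x freq, linear
  pmax_obs <- max(power)
  if (pmax_obs > 0) {
    power_db <- 10 * log10(power / pmax_obs) + top_db
    power_db[power_db < top_db - range_db] <- top_db - range_db
  } else {
    power_db <- array(top_db - range_db, dim(power))
  }
  structure(
    list(times = as.numeric(sg$t), freqs = as.numeric(sg$f[keep]),
         power = power, power_db = power_db,
         block_size = block, window_name = window,
         top_db = top_db, range_db = range_db),
    class = "spectrogram_result")
}

#' Per-block breathing-band power fraction
#'
#' Fraction of linear spectral power inside the breathing band (default
#' 4-5 Hz) relative to the total analysis band, per time block. Bands are
#' half-open: a bin at frequency f belongs to `[lo, hi)`, and the reference
#' total is `[0, max_freq)`. Blocks with zero total power return 0.
#'
#' @param spec A `spectrogram_result`.
#' @param band Numeric length-2, band edges in Hz.
#' @param max_freq Upper edge of the reference band, Hz.
#' @return Numeric vector, one fraction in `[0, 1]` per time block.
#' @export
breathing_band_fraction <- function(spec, band = c(4, 5), max_freq = 30) {
  stopifnot(inherits(spec, "spectrogram_result"), length(band) == 2)
  f <- spec$freqs
  if (band[1] < min(f) || band[2] > max(f) + 1e-9) {
    stop("band must lie within the spectrogram frequency axis")
  }
  in_band <- f >= band[1] & f < band[2]
  in_total <- f < max_freq
  num <- rowSums(spec$power[, in_band, drop = FALSE])
  den <- rowSums(spec$power[, in_total, drop = FALSE])
  frac <- ifelse(den > 0, num / den, 0)
  pmin(1, pmax(0, frac))
}

#' @export
print.spectrogram_result <- function(x, ...) {
  cat("<spectrogram_result> ", length(x$times), " blocks x ",
      length(x$freqs), " freqs (<= ", max(x$freqs), " Hz), block ",
      x$block_size, ", ", x$window_name, ", display [",
      x$top_db - x$range_db, ", ", x$top_db, "] dB\n", sep = "")
  invisible(x)
}

#' Render a spectrogram
#'
#' Image plot of the clipped dB matrix, time on x, frequency on y.
#'
#' @param x A `spectrogram_result`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.spectrogram_result <- function(x, ...) {
  graphics::image(x$times, x$freqs, x$power_db,
                  xlab = "Time (s)", ylab = "Frequency (Hz)",
                  useRaster = TRUE, ...)
  invisible(x)
}
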