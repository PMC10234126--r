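# EF voltage recordings: the raw input of the scoring pipeline.

#' Construct an EF recording
#'
#' A single-channel electric-field sensor voltage trace with sampling
#' metadata. Samples are hard-limited to the +/- 5 V range of the sensor
#' front end.
#'
#' @param samples Numeric vector of volts.
#' @param sampling_rate Sampling rate in Hz (acquisition hardware runs at
#'   2048 Hz; any rate `>= 64` Hz resolves the <= 30 Hz analysis band).
#' @param animal_id Animal identifier string.
#' @param session_date ISO date string.
#' @return An `ef_recording`.
#' @export
ef_recording <- function(samples, sampling_rate,
                         animal_id = "unknown", session_date = NA_character_) {
  stopifnot(is.numeric(samples), sampling_rate > 0)
  if (any(abs(samples) > 5 + 1e-12)) {
    stop("samples exceed the +/- 5 V input range; clip before constructing")
  }
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = sampling_rate,
         animal_id = animal_id,
         session_date = session_date,
         duration_s = length(samples) / sampling_rate),
    class = "ef_recording")
}

#' @export
print.ef_recording <- function(x, ...) {
  cat("<ef_recording> ", x$animal_id, ": ",
      round(x$duration_s, 1), " s at ", x$sampling_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Synthesize an EF trace from a behavioral state track
#'
#' Emission model: Gaussian sensor noise everywhere; SLEEP and QUIET_WAKE
#' intervals add the breathing oscillation (a `preset$breathing_freq` Hz
#' sinusoid of amplitude `preset$breathing_amp`, phase-continuous across the
#' session); ACTIVE_WAKE and GROOM intervals add high-amplitude broadband
#' movement noise; TWITCH intervals add a brief Hann-windowed 8 Hz
#' transient. The assembled trace is hard-clipped to +/- 5 V, matching the
#' sensor's range.
#'
#' @param track A `behavioral_track`.
#' @param preset The `sim_preset` providing emission parameters.
#' @param sampling_rate Hz, at least 64 (must resolve the 30 Hz band).
#' @param seed Integer seed for the emission noise.
#' @param animal_id,session_date Metadata passed to [ef_recording()].
#' @return An `ef_recording` of the same duration as the track.
#' @export
synthesize_ef_trace <- function(track, preset, sampling_rate = 256, seed = 1,
                                animal_id = "sim", session_date = NA_character_) {
  stopifnot(inherits(track, "behavioral_track"), inherits(preset, "sim_preset"))
  if (sampling_rate < 64) {
    stop("sampling_rate must be at least 64 Hz to resolve the 30 Hz band")
  }
  total <- attr(track, "total_duration_s")
  n <- round(total * sampling_rate)
  if (n == 0) {
    return(ef_recording(numeric(0), sampling_rate, animal_id, session_date))
  }

  stream <- rng_stream(derive_seed(seed, 5))
  x <- stream(rnorm, n, 0, preset$noise_sd)
  tt <- (seq_len(n) - 1) / sampling_rate
  phase <- stream(runif, 1, 0, 2 * pi)

  idx_of <- function(a, b) {
    i0 <- floor(a * sampling_rate) + 1
    i1 <- min(n, floor(b * sampling_rate))
    if (i1 < i0) integer(0) else i0:i1
  }
  for (i in seq_len(nrow(track))) {
    st <- track$state[i]
    idx <- idx_of(track$start_s[i], track$end_s[i])
    if (!length(idx)) next
    if (st %in% c("SLEEP", "QUIET_WAKE")) {
      x[idx] <- x[idx] +
        preset$breathing_amp * sin(2 * pi * preset$breathing_freq * tt[idx] + phase)
    } else if (st == "ACTIVE_WAKE") {
      x[idx] <- x[idx] + stream(rnorm, length(idx), 0, preset$active_amp_sd)
    } else if (st == "GROOM") {
      x[idx] <- x[idx] + stream(rnorm, length(idx), 0, preset$groom_amp_sd)
    } else if (st == "TWITCH") {
      w <- 0.5 * (1 - cos(2 * pi * seq_along(idx) / (length(idx) + 1)))
      x[idx] <- x[idx] +
        preset$twitch_amp * w * sin(2 * pi * 8 * tt[idx])
    }
  }
  x <- pmin(5, pmax(-5, x))
  ef_recording(x, sampling_rate, animal_id, session_date)
}
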