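# Ground-truth behavioral state tracks.
#
# A track is a contiguous, non-overlapping tiling of [0, total_duration_s]
# with states ACTIVE_WAKE, QUIET_WAKE, SLEEP, GROOM, TWITCH. TWITCH
# intervals are sub-second and occur only inside SLEEP spans; they are what
# the scoring pipeline must recognize as movements that do not terminate a
# sleep episode.

EF_STATES <- c("ACTIVE_WAKE", "QUIET_WAKE", "SLEEP", "GROOM", "TWITCH")
.STILL_STATES <- c("QUIET_WAKE", "SLEEP", "TWITCH")

#' Construct a behavioral state track
#'
#' @param intervals `data.frame` with columns `start_s`, `end_s`, `state`.
#' @param total_duration_s Total covered duration in seconds.
#' @return A `behavioral_track` (data.frame with a `total_duration_s`
#'   attribute).
#' @export
behavioral_track <- function(intervals, total_duration_s) {
  intervals <- as.data.frame(intervals)[, c("start_s", "end_s", "state")]
  attr(intervals, "total_duration_s") <- total_duration_s
  class(intervals) <- c("behavioral_track", "data.frame")
  validate_behavioral_track(intervals)
}

#' Validate a behavioral state track
#'
#' Enforces the track invariants: known states, strictly positive interval
#' lengths, contiguity covering `[0, total_duration_s]`, twitches of at most
#' 1 s flanked by sleep, and per-state occupancies summing to the total
#' duration.
#'
#' @param track A `behavioral_track`.
#' @param tol Numeric slack for floating-point contiguity checks.
#' @return The validated track.
#' @export
validate_behavioral_track <- function(track, tol = 1e-8) {
  stopifnot(inherits(track, "behavioral_track"))
  tot <- attr(track, "total_duration_s")
  if (nrow(track) == 0) {
    stopifnot(tot == 0)
    return(track)
  }
  stopifnot(
    all(track$state %in% EF_STATES),
    all(track$end_s > track$start_s),
    abs(track$start_s[1]) <= tol,
    abs(track$end_s[nrow(track)] - tot) <= tol,
    all(abs(track$start_s[-1] - track$end_s[-nrow(track)]) <= tol)
  )
  tw <- which(track$state == "TWITCH")
  if (length(tw)) {
    stopifnot(
      all(track$end_s[tw] - track$start_s[tw] <= 1 + tol),
      all(tw > 1), all(tw < nrow(track)),
      all(track$state[tw - 1] == "SLEEP"),
      all(track$state[tw + 1] == "SLEEP")
    )
  }
  occ <- state_occupancy(track)
  stopifnot(abs(sum(occ) - tot) <= tol * max(1, nrow(track)))
  track
}

#' Per-state occupancy of a track
#'
#' @param track A `behavioral_track`.
#' @return Named numeric vector of seconds spent in each state.
#' @export
state_occupancy <- function(track) {
  occ <- stats::setNames(numeric(length(EF_STATES)), EF_STATES)
  if (nrow(track)) {
    tab <- tapply(track$end_s - track$start_s, track$state, sum)
    occ[names(tab)] <- tab
  }
  occ
}

#' Ground-truth scored-eligible sleep of a track
#'
#' Direct occupancy tally, independent of the scoring pipeline: stillness
#' runs are maximal unions of SLEEP/QUIET_WAKE/TWITCH intervals; every run of
#' at least `still_s` seconds contributes `run - still_s` seconds. On
#' noise-free inputs this equals what the 60-s scoring rule can credit.
#'
#' @param track A `behavioral_track`.
#' @param still_s Qualification period in seconds (default 60).
#' @return Scored-eligible seconds of sleep in the track.
#' @export
eligible_sleep_s <- function(track, still_s = 60) {
  if (nrow(track) == 0) return(0)
  still <- track$state %in% .STILL_STATES
  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  if (!length(runs)) return(0)
  len <- track$end_s[ends[runs]] - track$start_s[starts[runs]]
  sum(pmax(0, len[len >= still_s] - still_s))
}

#' Simulate a behavioral state sequence
#'
#' Time-inhomogeneous semi-Markov draw. Wakefulness alternates bounded
#' QUIET_WAKE bouts with ACTIVE_WAKE/GROOM bouts; a sleep-entry hazard runs
#' during the active-type bouts at a stepwise per-hour intensity calibrated
#' in the preset (hours beyond the fifth reuse the fifth intensity). Sleep
#' spans have exponential durations with mean
#' `preset$mean_episode_duration`; sub-second twitches are inserted inside
#' sleep at `preset$twitch_rate_in_sleep` per minute, only after the 60 s
#' that the scoring rule needs to qualify the episode, so a twitch never
#' resets a qualification clock. Waking always begins with an active bout
#' (the movement that ends the episode under scoring).
#'
#' @param preset A `sim_preset`.
#' @param n_hours Number of hours to simulate (`>= 0`).
#' @param seed Integer seed; identical seed and parameters give
#'   bit-identical tracks.
#' @return A `behavioral_track`.
#' @export
simulate_state_sequence <- function(preset, n_hours, seed) {
  stopifnot(inherits(preset, "sim_preset"))
  if (n_hours < 0) stop("n_hours must be non-negative")
  total <- n_hours * 3600
  if (total == 0) {
    return(behavioral_track(
      data.frame(start_s = numeric(0), end_s = numeric(0),
                 state = character(0)), 0))
  }

  # independent sub-streams keep entry times, span durations, bout shapes
  # and twitches aligned across cohorts under common random numbers
  s_entry <- rng_stream(derive_seed(seed, 1))
  s_dur <- rng_stream(derive_seed(seed, 2))
  s_bout <- rng_stream(derive_seed(seed, 3))
  s_twitch <- rng_stream(derive_seed(seed, 4))

  entries <- preset$episode_rate_by_hour
  dur_mean <- preset$mean_episode_duration
  rho <- mean(preset$active_bout_range) /
    (mean(preset$active_bout_range) + mean(preset$quiet_bout_range))
  # hazard per active-wake second in each hour, accounting for the sleep
  # occupancy (own-hour plus previous-hour spillover) that entries remove
  # from the wake budget
  spill <- (dur_mean^2 / 3600) * (1 - exp(-3600 / dur_mean))
  sleep_h <- entries * (dur_mean - spill) +
    c(0, entries[-length(entries)]) * spill
  mu <- entries / (rho * pmax(600, 3600 - sleep_h))
  rate_at <- function(t) mu[min(length(mu), floor(t / 3600) + 1)]

  starts <- ends <- numeric(0)
  states <- character(0)
  emit <- function(a, b, st) {
    if (b - a > 1e-9) {
      starts[length(starts) + 1] <<- a
      ends[length(ends) + 1] <<- b
      states[length(states) + 1] <<- st
    }
  }

  t <- 0
  repeat {
    # --- wake phase: bouts until the entry hazard fires or time runs out
    budget <- s_entry(rexp, 1) # unit exponential, consumed in active bouts
    active <- TRUE             # recording and every waking start active
    entry <- NA_real_
    while (t < total && is.na(entry)) {
      if (active) {
        st <- if (s_bout(runif, 1) < preset$groom_prob) "GROOM" else "ACTIVE_WAKE"
        len <- s_bout(runif, 1, preset$active_bout_range[1],
                      preset$active_bout_range[2])
        b_end <- min(t + len, total)
        # consume hazard budget piecewise across hour boundaries
        seg <- t
        while (seg < b_end && is.na(entry)) {
          nxt <- min(b_end, (floor(seg / 3600) + 1) * 3600)
          need <- (nxt - seg) * rate_at(seg)
          if (budget <= need) {
            entry <- seg + budget / rate_at(seg)
          } else {
            budget <- budget - need
            seg <- nxt
          }
        }
        emit(t, if (is.na(entry)) b_end else entry, st)
        t <- if (is.na(entry)) b_end else entry
      } else {
        len <- s_bout(runif, 1, preset$quiet_bout_range[1],
                      preset$quiet_bout_range[2])
        b_end <- min(t + len, total)
        emit(t, b_end, "QUIET_WAKE")
        t <- b_end
      }
      active <- !active
    }
    if (t >= total) break

    # --- sleep span with embedded twitches
    span <- dur_mean * s_dur(rexp, 1)
    s_end <- min(t + span, total)
    tw <- .draw_twitches(t, s_end, preset$twitch_rate_in_sleep, s_twitch)
    cur <- t
    if (nrow(tw)) {
      for (i in seq_len(nrow(tw))) {
        emit(cur, tw$start[i], "SLEEP")
        emit(tw$start[i], tw$end[i], "TWITCH")
        cur <- tw$end[i]
      }
    }
    emit(cur, s_end, "SLEEP")
    t <- s_end
  }

  behavioral_track(
    data.frame(start_s = starts, end_s = ends, state = states,
               stringsAsFactors = FALSE),
    total)
}

# Twitches live in [span_start + still + 1, span_end - 0.5] so that they can
# never interfere with episode qualification; durations 0.2-0.6 s; overlaps
# thinned with a 1 s minimum spacing.
.draw_twitches <- function(span_start, span_end, rate_per_min, stream,
                           still = 60) {
  lo <- span_start + still + 1
  hi <- span_end - 0.5
  if (hi <= lo || rate_per_min <= 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  k <- stream(rpois, 1, rate_per_min / 60 * (hi - lo))
  if (k == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  st <- sort(stream(runif, k, lo, hi))
  du <- stream(runif, k, 0.2, 0.6)
  keep <- logical(k)
  last_end <- -Inf
  for (i in seq_len(k)) {
    if (st[i] > last_end + 1 && st[i] + du[i] < hi) {
      keep[i] <- TRUE
      last_end <- st[i] + du[i]
    }
  }
  data.frame(start = st[keep], end = (st + du)[keep])
}
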