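# The sleep-scoring rules. Sleep is defined behaviorally: after 60 s of
# continuous stillness (no movement event) the animal is considered asleep
# and sleep time starts accruing. Movements during sleep lasting at most 1 s
# are "twitches" and do not end the episode; the first longer movement ends
# it. Any movement during a not-yet-qualified stillness run resets the 60 s
# clock.

#' Score sleep episodes from movement events
#'
#' @param events `data.frame` of movement events (`start_s`, `end_s`,
#'   `duration_s`), non-overlapping, time-ordered, within `[0, duration_s]`.
#' @param duration_s Recording duration in seconds.
#' @param still_s Stillness qualification period (default 60 s).
#' @param twitch_limit_s Maximum duration of a movement that does not end an
#'   episode (default 1 s, inclusive).
#' @param credit_qualification If `TRUE`, credit sleep from the start of the
#'   stillness run instead of `still_s` seconds into it (the alternative
#'   reading of the rule; default `FALSE`).
#' @return `data.frame` of episodes: `qualification_start_s`,
#'   `sleep_start_s`, `end_s`, `credited_duration_s`, `twitch_count`.
#'   Episodes are non-overlapping, ordered, and have positive credit.
#' @export
score_sleep <- function(events, duration_s, still_s = 60, twitch_limit_s = 1,
                        credit_qualification = FALSE) {
  events <- .check_events(events, duration_s)
  ne <- nrow(events)
  qual_start <- sleep_start <- ep_end <- credited <- numeric(0)
  twitches <- integer(0)

  t <- 0      # start of the current stillness run
  i <- 1L     # next event index
  while (t < duration_s) {
    gap_end <- if (i <= ne) events$start_s[i] else duration_s
    if (gap_end - t >= still_s) {
      # qualified: walk forward through twitches until a terminator
      q <- t
      s <- if (credit_qualification) t else t + still_s
      tw <- 0L
      end <- duration_s
      t <- duration_s
      while (i <= ne) {
        if (events$duration_s[i] <= twitch_limit_s) {
          tw <- tw + 1L
          i <- i + 1L
        } else {
          end <- events$start_s[i]
          t <- events$end_s[i]
          i <- i + 1L
          break
        }
      }
      if (end > s) {
        qual_start <- c(qual_start, q)
        sleep_start <- c(sleep_start, s)
        ep_end <- c(ep_end, end)
        credited <- c(credited, end - s)
        twitches <- c(twitches, tw)
      }
    } else {
      # stillness broken before qualification: clock restarts after the event
      t <- if (i <= ne) events$end_s[i] else duration_s
      i <- i + 1L
    }
  }
  data.frame(qualification_start_s = qual_start,
             sleep_start_s = sleep_start,
             end_s = ep_end,
             credited_duration_s = credited,
             twitch_count = twitches)
}

#' Classify movement events against scored episodes
#'
#' Sets `event_class`: an event starting within an episode's credited span
#' is a `TWITCH` if its duration is at most `twitch_limit_s` (boundary
#' inclusive) and a `NON_TWITCH_SLEEP_MOVEMENT` otherwise (these are the
#' episode terminators); all remaining events are `WAKE_MOVEMENT`.
#'
#' @param events Movement-event `data.frame`.
#' @param episodes Episode `data.frame` from [score_sleep()].
#' @param twitch_limit_s Twitch duration limit (default 1 s).
#' @return The events with `event_class` filled in.
#' @export
classify_events <- function(events, episodes, twitch_limit_s = 1) {
  cls <- rep("WAKE_MOVEMENT", nrow(events))
  if (nrow(events) && nrow(episodes)) {
    for (k in seq_len(nrow(episodes))) {
      inside <- events$start_s >= episodes$sleep_start_s[k] &
        events$start_s <= episodes$end_s[k]
      cls[inside & events$duration_s <= twitch_limit_s] <- "TWITCH"
      cls[inside & events$duration_s > twitch_limit_s] <- "NON_TWITCH_SLEEP_MOVEMENT"
    }
  }
  events$event_class <- cls
  events
}

.check_events <- function(events, duration_s) {
  if (is.null(events) || nrow(events) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0)))
  }
  events <- as.data.frame(events)
  if (is.null(events$duration_s)) {
    events$duration_s <- events$end_s - events$start_s
  }
  if (any(events$end_s <= events$start_s)) {
    stop("events must have end_s > start_s")
  }
  if (any(events$start_s < 0) || any(events$end_s > duration_s + 1e-9)) {
    stop("events must lie within [0, duration_s]")
  }
  if (is.unsorted(events$start_s, strictly = FALSE)) {
    stop("events must be time-ordered")
  }
  if (nrow(events) > 1 &&
      any(events$start_s[-1] < events$end_s[-nrow(events)] - 1e-9)) {
    stop("events must be non-overlapping")
  }
  events
}

#' Ground-truth movement events of a simulated track
#'
#' Converts a `behavioral_track` into the event list an ideal detector
#' would produce: every ACTIVE_WAKE, GROOM and TWITCH interval becomes one
#' movement event (adjacent movement intervals merged).
#'
#' @param track A `behavioral_track`.
#' @return Movement-event `data.frame` suitable for [score_sleep()].
#' @export
track_events <- function(track) {
  mv <- track$state %in% c("ACTIVE_WAKE", "GROOM", "TWITCH")
  r <- rle(mv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  out <- data.frame(
    start_s = track$start_s[starts[runs]],
    end_s = track$end_s[ends[runs]])
  out$duration_s <- out$end_s - out$start_s
  out$peak_amplitude <- NA_real_
  out$event_class <- "UNCLASSIFIED"
  out
}
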