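# Hourly sleep metrics and their aggregation: per hour of recording, then
# across days within an animal, then across animals within a diet cohort.

#' Hourly sleep metrics from scored episodes
#'
#' Credited sleep seconds are apportioned to hour bins by actual overlap of
#' the credited span; each episode is counted in the hour containing its
#' `sleep_start_s` (keeping counts integral while conserving seconds);
#' twitches are counted in the hour containing their start. Hours beyond the
#' recorded duration are reported as `NA`, never as zero.
#'
#' @param episodes Episode `data.frame` from [score_sleep()].
#' @param duration_s Recording duration in seconds.
#' @param n_hours Number of hour bins to report (default 5).
#' @param events Optional classified event `data.frame` (see
#'   [classify_events()]); needed for twitch counts, otherwise `NA`.
#' @return `data.frame`: `hour` (1-based), `sleep_time_s`, `episode_count`,
#'   `mean_episode_duration_s`, `twitch_count`.
#' @export
hourly_metrics <- function(episodes, duration_s, n_hours = 5, events = NULL) {
  if (nrow(episodes)) {
    stopifnot(all(episodes$sleep_start_s >= 0),
              all(episodes$end_s <= duration_s + 1e-9))
  }
  full_hours <- floor(duration_s / 3600 + 1e-9)
  out <- data.frame(hour = seq_len(n_hours),
                    sleep_time_s = NA_real_,
                    episode_count = NA_integer_,
                    mean_episode_duration_s = NA_real_,
                    twitch_count = NA_integer_)
  have_twitches <- !is.null(events) && nrow(events) > 0 &&
    !is.null(events$event_class)
  for (h in seq_len(min(n_hours, full_hours))) {
    lo <- (h - 1) * 3600
    hi <- h * 3600
    if (nrow(episodes)) {
      ov <- pmax(0, pmin(episodes$end_s, hi) - pmax(episodes$sleep_start_s, lo))
      started <- episodes$sleep_start_s >= lo & episodes$sleep_start_s < hi
      out$sleep_time_s[h] <- sum(ov)
      out$episode_count[h] <- sum(started)
      out$mean_episode_duration_s[h] <-
        if (any(started)) mean(episodes$credited_duration_s[started]) else NA_real_
    } else {
      out$sleep_time_s[h] <- 0
      out$episode_count[h] <- 0L
    }
    out$twitch_count[h] <- if (!is.null(events)) {
      if (have_twitches) {
        sum(events$event_class == "TWITCH" &
              events$start_s >= lo & events$start_s < hi)
      } else 0L
    } else NA_integer_
  }
  stopifnot(all(out$sleep_time_s <= 3600 + 1e-9, na.rm = TRUE))
  out
}

#' Average daily metrics within an animal
#'
#' Unweighted mean across recording days, per hour; behavioral recordings
#' run over several subsequent days and are averaged per animal.
#'
#' @param daily_metrics `data.frame` of stacked [hourly_metrics()] outputs
#'   with an added `day` column.
#' @return `data.frame` with one row per hour: mean `sleep_time_s`,
#'   `episode_count`, `mean_episode_duration_s`, `twitch_count` across days
#'   (missing hours ignored in the mean; all-missing hours stay `NA`).
#' @export
aggregate_animal <- function(daily_metrics) {
  if (is.null(daily_metrics) || nrow(daily_metrics) == 0) {
    stop("no daily metrics to aggregate")
  }
  stopifnot(!is.null(daily_metrics$day), !is.null(daily_metrics$hour))
  num_mean <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  hours <- sort(unique(daily_metrics$hour))
  rows <- lapply(hours, function(h) {
    d <- daily_metrics[daily_metrics$hour == h, ]
    data.frame(hour = h,
               sleep_time_s = num_mean(d$sleep_time_s),
               episode_count = num_mean(d$episode_count),
               mean_episode_duration_s = num_mean(d$mean_episode_duration_s),
               twitch_count = num_mean(d$twitch_count))
  })
  do.call(rbind, rows)
}

#' Cohort-level summary of per-animal metrics
#'
#' Group mean and standard error (SEM = SD / sqrt(n)) of hourly sleep time,
#' episodes per hour, and each hour's episode count. With a single animal
#' the mean is reported and the SEM is `NA` with a warning.
#'
#' @param animal_metrics `data.frame` of stacked [aggregate_animal()]
#'   outputs with an added `animal_id` column.
#' @param group_label Cohort label carried into the summary.
#' @return A `cohort_summary`: list with `group_label`, `n_animals`,
#'   `mean_sleep_s_per_h`, `sem_sleep_s_per_h`, `mean_episodes_per_h`,
#'   `sem_episodes_per_h`, `per_hour` (data.frame of hour, mean, sem), and
#'   `per_animal` (the per-animal scalars).
#' @export
cohort_summary <- function(animal_metrics, group_label = "cohort") {
  stopifnot(!is.null(animal_metrics$animal_id))
  ids <- unique(animal_metrics$animal_id)
  n <- length(ids)
  per_animal <- do.call(rbind, lapply(ids, function(id) {
    d <- animal_metrics[animal_metrics$animal_id == id, ]
    data.frame(animal_id = id,
               sleep_s_per_h = mean(d$sleep_time_s, na.rm = TRUE),
               episodes_per_h = mean(d$episode_count, na.rm = TRUE))
  }))
  sem <- function(x) {
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  if (n < 2) warning("single-animal cohort: SEM undefined")
  hours <- sort(unique(animal_metrics$hour))
  per_hour <- do.call(rbind, lapply(hours, function(h) {
    x <- animal_metrics$episode_count[animal_metrics$hour == h]
    data.frame(hour = h, mean_episode_count = mean(x, na.rm = TRUE),
               sem_episode_count = sem(x[!is.na(x)]))
  }))
  structure(
    list(group_label = group_label,
         n_animals = n,
         mean_sleep_s_per_h = mean(per_animal$sleep_s_per_h),
         sem_sleep_s_per_h = sem(per_animal$sleep_s_per_h),
         mean_episodes_per_h = mean(per_animal$episodes_per_h),
         sem_episodes_per_h = sem(per_animal$episodes_per_h),
         per_hour = per_hour,
         per_animal = per_animal),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> ", x$group_label, " (n = ", x$n_animals, ")\n",
      "  sleep: ", round(x$mean_sleep_s_per_h, 1), " +/- ",
      round(x$sem_sleep_s_per_h, 1), " s/h (SEM)\n",
      "  episodes: ", round(x$mean_episodes_per_h, 2), " +/- ",
      round(x$sem_episodes_per_h, 2), " per h\n", sep = "")
  invisible(x)
}
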