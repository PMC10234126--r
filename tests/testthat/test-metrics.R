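ep_df <- function(sleep_start, end) {
  data.frame(qualification_start_s = sleep_start - 60,
             sleep_start_s = sleep_start, end_s = end,
             credited_duration_s = end - sleep_start,
             twitch_count = 0L)
}

test_that("hourly metrics: containment, boundary split, missing hours", {
  # one episode credited [100, 700]: all in hour 1
  m <- hourly_metrics(ep_df(100, 700), 5 * 3600)
  expect_equal(m$sleep_time_s, c(600, 0, 0, 0, 0))
  expect_equal(m$episode_count, c(1, 0, 0, 0, 0))
  expect_equal(m$mean_episode_duration_s[1], 600)

  # episode credited [3500, 3700] splits seconds across hours 1 and 2 but
  # counts only in hour 1 (its sleep onset hour)
  m2 <- hourly_metrics(ep_df(3500, 3700), 5 * 3600)
  expect_equal(m2$sleep_time_s[1:2], c(100, 100))
  expect_equal(m2$episode_count[1:2], c(1, 0))

  # a 2 h recording reports hours 3-5 as missing, not zero
  m3 <- hourly_metrics(ep_df(100, 700), 2 * 3600)
  expect_equal(m3$sleep_time_s[1:2], c(600, 0))
  expect_true(all(is.na(m3$sleep_time_s[3:5])))
  expect_true(all(is.na(m3$episode_count[3:5])))
})

test_that("hour binning conserves credited sleep on random episode sets", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(1:12, 1)
    qs <- sort(runif(n, 0, 5 * 3600 - 400))
    # enforce separation so episodes do not overlap
    qs <- qs + seq(0, by = 400, length.out = n) * 0
    qs <- cumsum(c(qs[1], pmax(diff(qs), 150)))
    ends <- qs + runif(n, 61, 140)
    ok <- ends <= 5 * 3600
    ep <- ep_df((qs + 60)[ok], ends[ok])
    m <- hourly_metrics(ep, 5 * 3600)
    expect_equal(sum(m$sleep_time_s), sum(ep$credited_duration_s),
                 tolerance = 1e-9)
    expect_equal(sum(m$episode_count), nrow(ep))
  }
})

test_that("twitch counts land in the hour of the twitch start", {
  ev <- data.frame(start_s = c(500, 3700, 3800), end_s = c(500.5, 3700.4, 3802),
                   duration_s = c(0.5, 0.4, 2))
  ep <- score_sleep(ev, 3 * 3600)
  evc <- classify_events(ev, ep)
  m <- hourly_metrics(ep, 3 * 3600, n_hours = 3, events = evc)
  expect_equal(m$twitch_count[1:2], c(1, 1))
})

test_that("animal aggregation is the unweighted day mean", {
  d1 <- hourly_metrics(ep_df(100, 700), 5 * 3600)
  d1$day <- 1
  # single day: identity
  one <- aggregate_animal(d1)
  expect_equal(one$sleep_time_s, d1$sleep_time_s)

  d2 <- hourly_metrics(ep_df(200, 1400), 5 * 3600)
  d2$day <- 2
  two <- aggregate_animal(rbind(d1, d2))
  expect_equal(two$sleep_time_s[1], (600 + 1200) / 2)
  expect_equal(two$episode_count[1], 1)

  # random inputs equal independently computed column means
  set.seed(4)
  days <- lapply(1:4, function(d) {
    m <- hourly_metrics(ep_df(100 * d, 100 * d + 600), 5 * 3600)
    m$day <- d
    m
  })
  agg <- aggregate_animal(do.call(rbind, days))
  for (h in 1:5) {
    vals <- vapply(days, function(m) m$sleep_time_s[h], numeric(1))
    expect_equal(agg$sleep_time_s[h], mean(vals))
  }
  expect_error(aggregate_animal(NULL), "no daily metrics")
})

test_that("cohort summary computes SEM = SD/sqrt(n) and flags n = 1", {
  mk <- function(id, sleep) {
    data.frame(animal_id = id, hour = 1:5, sleep_time_s = sleep,
               episode_count = 2, mean_episode_duration_s = 300,
               twitch_count = 1)
  }
  am <- rbind(mk("a", 600), mk("b", 900), mk("c", 1200))
  cs <- cohort_summary(am, "demo")
  expect_equal(cs$n_animals, 3)
  expect_equal(cs$mean_sleep_s_per_h, 900)
  expect_equal(cs$sem_sleep_s_per_h, sd(c(600, 900, 1200)) / sqrt(3))
  # identical animals -> SEM 0
  cs0 <- cohort_summary(rbind(mk("a", 700), mk("b", 700)), "same")
  expect_equal(cs0$sem_sleep_s_per_h, 0)
  expect_equal(cs0$per_hour$sem_episode_count, rep(0, 5))
  expect_warning(cohort_summary(mk("solo", 500), "solo"), "SEM undefined")
})
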