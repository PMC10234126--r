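ev_df <- function(start, end) {
  data.frame(start_s = start, end_s = end, duration_s = end - start)
}

test_that("an event-free hour yields one episode credited 3540 s", {
  ep <- score_sleep(ev_df(numeric(0), numeric(0)), 3600)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$qualification_start_s, 0)
  expect_equal(ep$sleep_start_s, 60)
  expect_equal(ep$end_s, 3600)
  expect_equal(ep$credited_duration_s, 3540)
  # inclusive alternative credits the qualification window too
  ep2 <- score_sleep(ev_df(numeric(0), numeric(0)), 3600,
                     credit_qualification = TRUE)
  expect_equal(ep2$credited_duration_s, 3600)
})

test_that("movements every 30 s prevent any episode", {
  starts <- seq(0, 3570, by = 30)
  ep <- score_sleep(ev_df(starts, starts + 2), 3600)
  expect_equal(nrow(ep), 0)
})

test_that("the 1 s limit separates twitches from terminators", {
  # stillness from 0; asleep at 60; 0.8 s movement at 500 is a twitch;
  # 1.5 s movement at 900 ends the episode there
  ep <- score_sleep(ev_df(c(500, 900), c(500.8, 901.5)), 3600)
  expect_equal(nrow(ep), 2) # second episode qualifies after 901.5
  expect_equal(ep$sleep_start_s[1], 60)
  expect_equal(ep$end_s[1], 900)
  expect_equal(ep$twitch_count[1], 1)
  expect_equal(ep$qualification_start_s[2], 901.5)

  # duration exactly 1.0 s inside an episode is a twitch (inclusive limit)
  ep3 <- score_sleep(ev_df(500, 501), 3600)
  expect_equal(nrow(ep3), 1)
  expect_equal(ep3$twitch_count, 1)
  expect_equal(ep3$end_s, 3600)
})

test_that("a movement during qualification resets the stillness clock", {
  # 0.5 s movement at t = 50: stillness restarts at 50.5
  ep <- score_sleep(ev_df(50, 50.5), 200)
  expect_equal(ep$qualification_start_s, 50.5)
  expect_equal(ep$sleep_start_s, 110.5)
  expect_equal(ep$credited_duration_s, 200 - 110.5)
})

test_that("malformed event lists are rejected", {
  expect_error(score_sleep(ev_df(c(10, 5), c(12, 8)), 100), "ordered")
  expect_error(score_sleep(ev_df(c(5, 6), c(8, 9)), 100), "overlap")
  expect_error(score_sleep(ev_df(5, 120), 100), "within")
  expect_error(score_sleep(ev_df(5, 4), 100), "end_s")
})

test_that("scoring matches the second-by-second state-machine oracle", {
  set.seed(99)
  for (rep in 1:200) {
    dur <- 2000
    ev <- random_event_set(dur, n_target = sample(2:25, 1))
    got <- score_sleep(ev, dur)
    want <- grid_score_oracle(ev, dur, dt = 0.25)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$qualification_start_s, want$qualification_start_s)
      expect_equal(got$sleep_start_s, want$sleep_start_s)
      expect_equal(got$end_s, want$end_s)
      expect_equal(got$credited_duration_s, want$credited_duration_s)
      expect_equal(got$twitch_count, want$twitch_count)
    }
    # structural invariants
    if (nrow(got) > 1) {
      expect_true(all(got$qualification_start_s[-1] >= got$end_s[-nrow(got)]))
    }
    expect_true(all(got$credited_duration_s > 0))
    expect_equal(got$sleep_start_s, got$qualification_start_s + 60)
  }
})

test_that("event classification respects containment and the twitch limit", {
  ev <- ev_df(c(500, 900, 2000), c(500.9, 901.5, 2000.9))
  ep <- score_sleep(ev, 3600)
  cls <- classify_events(ev, ep)$event_class
  expect_equal(cls[1], "TWITCH")                      # 0.9 s inside episode
  expect_equal(cls[2], "NON_TWITCH_SLEEP_MOVEMENT")   # the terminator
  expect_equal(cls[3], "TWITCH")                      # inside 2nd episode
  # same 0.9 s event with no episode at all is a wake movement
  busy <- ev_df(seq(0, 3580, 20), seq(0, 3580, 20) + 2)
  ep0 <- score_sleep(busy, 3600)
  cls0 <- classify_events(ev_df(500.5, 501.4), ep0)$event_class
  expect_equal(cls0, "WAKE_MOVEMENT")
})

test_that("noise-free identity: scored credit = eligible stillness - 60 per episode", {
  for (g in c("Control", "ID")) {
    p <- preset_for(g)
    for (seed in c(2, 12, 22)) {
      tr <- simulate_state_sequence(p, 5, seed = seed)
      ep <- score_sleep(track_events(tr), attr(tr, "total_duration_s"))
      expect_equal(sum(ep$credited_duration_s), eligible_sleep_s(tr),
                   tolerance = 1e-9)
      # and the twitch tally matches the track's twitch intervals
      expect_equal(sum(ep$twitch_count), sum(tr$state == "TWITCH"))
    }
  }
})
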