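test_that("envelope of silence is zero and envelopes are never negative", {
  rec <- ef_recording(numeric(640), 64)
  env <- movement_envelope(rec)
  expect_true(all(env$values == 0))
  set.seed(1)
  env2 <- movement_envelope(ef_recording(pmin(5, pmax(-5, rnorm(640))), 64))
  expect_true(all(env2$values >= 0))
  expect_length(env2$values, 640)
  expect_error(movement_envelope(ef_recording(numeric(0), 64)), "empty")
})

test_that("a burst's envelope peaks at the burst, matching a windowed-RMS oracle", {
  fs <- 64
  x <- numeric(fs * 20)
  idx <- (10 * fs):(10.5 * fs) # 0.5 s burst of 3 V at t = 10 s
  x[idx] <- 3
  env <- movement_envelope(ef_recording(x, fs), smoothing_window_s = 0.25)
  peak_t <- which.max(env$values) / fs
  expect_gte(peak_t, 10 - 0.25)
  expect_lte(peak_t, 10.5 + 0.25)
  # direct windowed-RMS oracle at a handful of positions
  w <- round(0.25 * fs)
  for (i in c(200, 640, 660, 700, 1000)) {
    lo <- max(1, i - w %/% 2)
    hi <- min(length(x), i - w %/% 2 + w - 1)
    expect_equal(env$values[i], sqrt(mean(x[lo:hi]^2)), tolerance = 1e-12)
  }
})

test_that("envelope scales linearly with amplitude", {
  set.seed(5)
  x <- rnorm(64 * 10, 0, 0.3) # small enough that 3x stays inside +/- 5 V
  e1 <- movement_envelope(ef_recording(x, 64))$values
  e3 <- movement_envelope(ef_recording(3 * x, 64))$values
  expect_equal(e3, 3 * e1, tolerance = 1e-9)
})

make_env <- function(v, rate) {
  structure(list(values = v, rate = rate, smoothing_window_s = 0.25),
            class = "envelope_series")
}

test_that("detector edge cases: silence, merging, MAD fallback", {
  # flat zero envelope -> MAD fallback path, no events
  expect_warning(ev0 <- detect_movement_events(make_env(numeric(500), 50)),
                 "MAD")
  expect_equal(nrow(ev0), 0)

  # two bursts separated by 0.1 s merge into one event at merge_gap_s = 0.2
  set.seed(8)
  v <- abs(rnorm(50 * 30, 0, 0.01)) + 0.05
  v[701:750] <- 2   # burst 1: 14.00-15.00 s
  v[756:805] <- 2   # burst 2: 15.10-16.10 s (0.1 s gap)
  ev <- detect_movement_events(make_env(v, 50))
  expect_equal(nrow(ev), 1)
  expect_lt(ev$start_s, 14.1)
  expect_gt(ev$end_s, 16)
  expect_equal(ev$event_class, "UNCLASSIFIED")
  # with a smaller merge gap they stay separate
  ev2 <- detect_movement_events(make_env(v, 50), merge_gap_s = 0.05)
  expect_equal(nrow(ev2), 2)
})

test_that("detector equals the sample-by-sample brute-force scanner", {
  rate <- 50
  for (seed in 1:100) {
    set.seed(seed)
    n <- rate * 20
    v <- abs(rnorm(n, 0, 0.02)) + 0.04
    # plant a random number of bursts of random widths/heights
    for (b in seq_len(sample(0:5, 1))) {
      a <- sample(n - 60, 1)
      wdt <- sample(3:40, 1)
      v[a:(a + wdt)] <- v[a:(a + wdt)] + runif(1, 0.5, 3)
    }
    got <- detect_movement_events(make_env(v, rate))
    want <- brute_force_detect(v, rate)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start_s, want$start_s, tolerance = 1e-12)
      expect_equal(got$end_s, want$end_s, tolerance = 1e-12)
    }
  }
})

test_that("event count is monotone non-increasing in threshold_k", {
  set.seed(33)
  rate <- 50
  v <- abs(rnorm(rate * 60, 0, 0.05)) + 0.04
  for (b in 1:12) {
    a <- sample(rate * 60 - 40, 1)
    v[a:(a + sample(3:30, 1))] <- runif(1, 0.2, 2)
  }
  counts <- vapply(c(2, 3, 5, 8, 12),
                   function(k) nrow(detect_movement_events(make_env(v, rate),
                                                           threshold_k = k)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("event boundaries agree across sampling rates for band-limited input", {
  # the same continuous-time signal (breathing background plus two tonal
  # movement bursts) sampled at three rates must give matching event sets
  signal_at <- function(fs) {
    t <- (0:(fs * 120 - 1)) / fs
    x <- 0.05 * sin(2 * pi * 4.5 * t)
    b1 <- t >= 40 & t < 43
    b2 <- t >= 83 & t < 88
    x[b1] <- x[b1] + 2 * sin(2 * pi * 10 * t[b1])
    x[b2] <- x[b2] + 1.5 * sin(2 * pi * 7 * t[b2])
    ef_recording(x, fs)
  }
  res <- lapply(c(256, 512, 2048), function(fs) {
    detect_movement_events(movement_envelope(lowpass_filter(signal_at(fs))))
  })
  for (r in res[-1]) {
    expect_equal(nrow(r), nrow(res[[1]]))
    expect_true(all(abs(r$start_s - res[[1]]$start_s) <= 0.25))
    expect_true(all(abs(r$end_s - res[[1]]$end_s) <= 0.25))
  }
  expect_equal(nrow(res[[1]]), 2)
})
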