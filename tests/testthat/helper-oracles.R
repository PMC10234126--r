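# Independent oracles used across the suite. Each re-derives a quantity by
# the most naive route available (sample-by-sample scans, per-step state
# machines, textbook sums of squares) so the vectorized implementations are
# checked against genuinely different code paths.

# Sample-by-sample movement-event scanner: walk the envelope one sample at
# a time, collecting runs above the hysteresis exit level, then keep runs
# touching the entry threshold, merge close runs, prune short ones.
brute_force_detect <- function(v, rate, threshold_k = 5, merge_gap_s = 0.2,
                               min_duration_s = 0.05, fallback = 0.5) {
  seg <- round(rate)
  ns <- floor(length(v) / seg)
  means <- vapply(seq_len(ns),
                  function(i) mean(v[((i - 1) * seg + 1):(i * seg)]),
                  numeric(1))
  cut <- stats::quantile(means, 0.1, names = FALSE)
  bl <- unlist(lapply(which(means <= cut),
                      function(i) v[((i - 1) * seg + 1):(i * seg)]))
  med <- stats::median(bl)
  dv <- stats::mad(bl)
  if (dv == 0) {
    upper <- fallback
    lower <- fallback / 2
  } else {
    upper <- med + threshold_k * dv
    lower <- med + threshold_k / 2 * dv
  }
  runs <- list()
  in_run <- FALSE
  for (i in seq_along(v)) {
    if (!in_run && v[i] > lower) {
      in_run <- TRUE
      a <- i
    }
    if (in_run && (v[i] <= lower || i == length(v))) {
      b <- if (v[i] <= lower) i - 1 else i
      runs[[length(runs) + 1]] <- c(a, b)
      in_run <- FALSE
    }
  }
  runs <- Filter(function(r) any(v[r[1]:r[2]] > upper), runs)
  if (!length(runs)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    prev <- merged[[length(merged)]]
    if ((r[1] - prev[2] - 1) / rate < merge_gap_s) {
      merged[[length(merged)]] <- c(prev[1], r[2])
    } else {
      merged[[length(merged) + 1]] <- r
    }
  }
  out <- do.call(rbind, lapply(merged, function(r) {
    data.frame(start_s = (r[1] - 1) / rate, end_s = r[2] / rate)
  }))
  out <- out[out$end_s - out$start_s >= min_duration_s, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-time-step sleep-scoring state machine. Exact when all event times are
# multiples of dt. Counts a twitch at the first step of each short event
# inside sleep; a long event ends the episode at its start.
grid_score_oracle <- function(events, duration_s, dt = 0.25, still = 60,
                              limit = 1) {
  nst <- round(duration_s / dt)
  moving <- integer(nst)
  if (nrow(events)) {
    for (k in seq_len(nrow(events))) {
      a <- round(events$start_s[k] / dt)
      b <- round(events$end_s[k] / dt)
      if (b >= a + 1) moving[(a + 1):b] <- k
    }
  }
  asleep <- FALSE
  still_len <- 0
  qual_start <- sleep_start <- NA_real_
  tw <- 0L
  eps <- list()
  push <- function(end) {
    if (end > sleep_start) {
      eps[[length(eps) + 1]] <<- data.frame(
        qualification_start_s = qual_start, sleep_start_s = sleep_start,
        end_s = end, credited_duration_s = end - sleep_start,
        twitch_count = tw)
    }
  }
  for (s in seq_len(nst)) {
    mv <- moving[s]
    if (!asleep) {
      if (mv == 0) {
        still_len <- still_len + dt
        if (still_len >= still - 1e-9) {
          asleep <- TRUE
          qual_start <- s * dt - still_len
          sleep_start <- qual_start + still
          tw <- 0L
        }
      } else {
        still_len <- 0
      }
    } else if (mv != 0) {
      if (events$duration_s[mv] > limit) {
        push(events$start_s[mv])
        asleep <- FALSE
        still_len <- 0
      } else if (s == round(events$start_s[mv] / dt) + 1) {
        tw <- tw + 1L
      }
    }
  }
  if (asleep) push(duration_s)
  if (!length(eps)) {
    return(data.frame(qualification_start_s = numeric(0),
                      sleep_start_s = numeric(0), end_s = numeric(0),
                      credited_duration_s = numeric(0),
                      twitch_count = integer(0)))
  }
  out <- do.call(rbind, eps)
  rownames(out) <- NULL
  out
}

# Random non-overlapping event sets on a 0.25 s grid: a mix of sub-second
# twitch-like events and longer movements.
random_event_set <- function(duration_s, n_target, dt = 0.25) {
  t <- 0
  rows <- list()
  while (length(rows) < n_target) {
    gap <- dt * sample(1:400, 1)
    dur <- dt * sample(c(1:3, 5:12), 1) # 0.25-0.75 s or 1.25-3 s
    if (t + gap + dur > duration_s) break
    rows[[length(rows) + 1]] <- data.frame(start_s = t + gap,
                                           end_s = t + gap + dur)
    t <- t + gap + dur
  }
  if (!length(rows)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0)))
  }
  ev <- do.call(rbind, rows)
  ev$duration_s <- ev$end_s - ev$start_s
  ev
}

# Single-block amplitude spectrum via the plain DFT definition.
naive_dft_amplitude <- function(x, fs) {
  n <- length(x)
  k <- 0:(n %/% 2)
  amp <- vapply(k, function(kk) {
    ph <- -2i * pi * kk * (0:(n - 1)) / n
    Mod(sum(x * exp(ph))) * 2 / n
  }, numeric(1))
  list(freq = k * fs / n, amp = amp)
}

# Textbook one-way ANOVA sums of squares.
anova_ss_oracle <- function(groups) {
  y <- unlist(groups)
  grand <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1
  df2 <- length(y) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = 1 - pf(f, df1, df2))
}

# Kruskal-Wallis H from explicit rank sums (no tie correction; callers use
# untied data).
kruskal_oracle <- function(groups) {
  y <- unlist(groups)
  r <- rank(y)
  n <- length(y)
  idx <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(seq_along(groups), function(i) {
      ri <- sum(r[idx == i])
      ri^2 / sum(idx == i)
    }, numeric(1))) - 3 * (n + 1)
  h
}
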