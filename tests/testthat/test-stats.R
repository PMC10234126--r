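test_that("summary t-test matches raw-data t-tests to numerical precision", {
  set.seed(31)
  for (rep in 1:100) {
    n1 <- sample(3:12, 1)
    n2 <- sample(3:12, 1)
    x <- rnorm(n1, 10, 2)
    y <- rnorm(n2, 10 + runif(1, -3, 3), 2)
    r <- t_test_from_summary(mean(x), sd(x) / sqrt(n1), n1,
                             mean(y), sd(y) / sqrt(n2), n2)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_lt(abs(r$p_value - ref$p.value), 1e-9)
    expect_lt(abs(r$statistic - unname(ref$statistic)), 1e-9)
    rw <- t_test_from_summary(mean(x), sd(x) / sqrt(n1), n1,
                              mean(y), sd(y) / sqrt(n2), n2, welch = TRUE)
    refw <- t.test(x, y)
    expect_lt(abs(rw$p_value - refw$p.value), 1e-9)
  }
})

test_that("summary t-test handles nulls and degenerate variance", {
  r <- t_test_from_summary(5, 1, 6, 5, 1, 6)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_warning(z <- t_test_from_summary(5, 0, 6, 5, 0, 6), "zero pooled")
  expect_equal(z$p_value, 1)
  expect_error(t_test_from_summary(5, 0, 6, 6, 0, 6), "undefined")
})

test_that("one-way ANOVA equals the textbook sums-of-squares oracle", {
  set.seed(7)
  for (rep in 1:50) {
    groups <- lapply(1:sample(2:5, 1), function(i) rnorm(sample(3:9, 1), i / 2))
    r <- one_way_anova(groups)
    o <- anova_ss_oracle(groups)
    expect_lt(abs(r$statistic - o$F), 1e-9)
    expect_lt(abs(r$p_value - o$p), 1e-9)
    expect_true(r$power >= 0 && r$power <= 1)
  }
  # identical groups: F = 0, p = 1
  r0 <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
})

test_that("Holm-Sidak adjustment is monotone and bounded by raw p-values", {
  set.seed(12)
  groups <- list(a = rnorm(6), b = rnorm(6, 1), c = rnorm(6, 3), d = rnorm(6))
  ph <- one_way_anova(groups)$posthoc
  expect_equal(nrow(ph), 6)
  expect_true(all(ph$p_adj >= ph$p_raw - 1e-12))
  expect_true(all(ph$p_adj <= 1))
  # step-down: ordering of adjusted p follows ordering of raw p
  expect_true(all(diff(ph$p_adj[order(ph$p_raw)]) >= -1e-12))
  # sanity: the wildly separated pair is still significant after adjustment
  expect_lt(ph$p_adj[ph$group1 == "b" & ph$group2 == "c"], 0.05)
})

test_that("rank ANOVA equals the explicit rank-sum computation", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  r <- rank_anova(g)
  expect_lt(abs(r$statistic - kruskal_oracle(g)), 1e-9)
  set.seed(3)
  pool <- sample(1:1000, 15) # untied: the oracle has no tie correction
  g2 <- split(pool, rep(1:3, each = 5))
  expect_lt(abs(rank_anova(g2)$statistic - kruskal_oracle(g2)), 1e-9)
  # monotone shift increases H
  h1 <- rank_anova(list(1:4, 2:5 + 0.5))$statistic
  h2 <- rank_anova(list(1:4, 2:5 + 10))$statistic
  expect_gt(h2, h1)
  expect_warning(rt <- rank_anova(list(c(2, 2), c(2, 2))), "tied")
  expect_equal(rt$p_value, 1)
})

test_that("RM ANOVA matches the partitioned sums-of-squares via aov()", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    k <- sample(3:6, 1)
    mat <- matrix(rnorm(n * k), n, k) + outer(rnorm(n), rnorm(k), "+")
    r <- rm_anova(mat)
    d <- data.frame(y = as.vector(mat),
                    subj = factor(rep(seq_len(n), k)),
                    time = factor(rep(seq_len(k), each = n)))
    ref <- summary(aov(y ~ time + Error(subj), data = d))
    tab <- ref[["Error: Within"]][[1]]
    expect_lt(abs(r$statistic - tab[["F value"]][1]), 1e-9)
    expect_lt(abs(r$p_value - tab[["Pr(>F)"]][1]), 1e-9)
  }
  # identical columns: F = 0, p = 1 (flagged degenerate: rows are constant)
  m0 <- matrix(rnorm(6), 6, 4)
  expect_warning(r0 <- rm_anova(m0), "degenerate")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_error(rm_anova(matrix(1:4, 1)), "at least 2")
})

test_that("post-hoc power grows with effect size and sample size", {
  pw_eff <- vapply(c(0.5, 1, 2, 4), function(d) {
    t_test_from_summary(0, 1 / sqrt(6), 6, d, 1 / sqrt(6), 6)$power
  }, numeric(1))
  expect_true(all(diff(pw_eff) > 0))
  pw_n <- vapply(c(4, 8, 16, 32), function(n) {
    t_test_from_summary(0, 1 / sqrt(n), n, 1.5, 1 / sqrt(n), n)$power
  }, numeric(1))
  expect_true(all(diff(pw_n) > 0))
  expect_true(all(c(pw_eff, pw_n) >= 0 & c(pw_eff, pw_n) <= 1))
})

test_that("per-hour comparison is the hour-restricted one-way ANOVA", {
  set.seed(9)
  mk <- function(g, mu) {
    do.call(rbind, lapply(1:6, function(a) {
      data.frame(animal_id = paste0(g, a), hour = 1:5,
                 episode_count = rnorm(5, mu), sleep_time_s = 0,
                 mean_episode_duration_s = 0, twitch_count = 0)
    }))
  }
  cohorts <- list(A = mk("A", 1), B = mk("B", 2), C = mk("C", 1.5))
  r <- per_hour_comparison(cohorts, 2)
  direct <- one_way_anova(lapply(cohorts, function(d) d$episode_count[d$hour == 2]))
  expect_equal(r$statistic, direct$statistic)
  expect_equal(r$p_value, direct$p_value)
})

test_that("diet effects in simulated latency series are detected repeatedly", {
  hits_rm <- 0
  hits_t <- 0
  for (s in 1:6) {
    ctrl <- simulate_latency_table(preset_for("Control", "M"), 6, 8,
                                   seed = derive_seed(300, s, 1))
    idt <- simulate_latency_table(preset_for("ID", "M"), 6, 8,
                                  seed = derive_seed(300, s, 2))
    cm <- latency_cohort_means(ctrl)
    im <- latency_cohort_means(idt)
    # within-subject decline of the ID cohort across weeks
    mat <- matrix(im$sessions$session_mean_s, nrow = 6) # animals x weeks
    if (rm_anova(mat)$p_value < 0.05) hits_rm <- hits_rm + 1
    # between-diet contrast on subject means
    a <- tapply(cm$sessions$session_mean_s, cm$sessions$animal_id, mean)
    b <- tapply(im$sessions$session_mean_s, im$sessions$animal_id, mean)
    r <- t_test_from_summary(mean(a), sd(a) / sqrt(6), 6,
                             mean(b), sd(b) / sqrt(6), 6)
    if (r$p_value < 0.05) hits_t <- hits_t + 1
  }
  expect_gte(hits_rm, 5)
  expect_gte(hits_t, 5)
})
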