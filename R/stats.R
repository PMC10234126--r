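# Statistical comparisons used for cohort contrasts: two-sample t from
# summary statistics, one-way ANOVA with Holm-Sidak post-hoc pairs, ANOVA
# on ranks (Kruskal-Wallis), one-way repeated-measures ANOVA, and post-hoc
# power at alpha = 0.05 from the noncentral t/F at the observed effect (the
# convention of the desktop statistics packages these analyses mirror).

.test_result <- function(test_name, statistic, df, p_value, power = NA_real_,
                         group_ns = NULL, effect_summary = "", posthoc = NULL) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(
    list(test_name = test_name, statistic = statistic, df = df,
         p_value = min(1, p_value), power = power, group_ns = group_ns,
         effect_summary = effect_summary, posthoc = posthoc),
    class = "ef_test_result")
}

#' @export
print.ef_test_result <- function(x, ...) {
  cat("<", x$test_name, "> statistic = ", signif(x$statistic, 4),
      ", df = ", paste(signif(x$df, 4), collapse = ", "),
      ", p = ", signif(x$p_value, 3), sep = "")
  if (!is.na(x$power)) cat(", power = ", signif(x$power, 3), sep = "")
  cat("\n")
  if (nzchar(x$effect_summary)) cat("  ", x$effect_summary, "\n", sep = "")
  invisible(x)
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance Student's t computed from group means, SEMs and sizes
#' (SD recovered as SEM * sqrt(n)); optionally Welch. Post-hoc power is
#' taken from the noncentral t distribution at the observed effect with
#' alpha = 0.05. `paired = TRUE` treats the summaries as describing the
#' paired differences' components and requires equal n (the correlation
#' term cannot be recovered from marginal summaries, so the difference SD
#' uses the conservative independent-components form).
#'
#' @param mean1,sem1,n1 First group: mean, SEM, size (`n >= 2`).
#' @param mean2,sem2,n2 Second group.
#' @param paired Paired design flag.
#' @param welch Use Welch's unequal-variance form instead of pooling.
#' @param alpha Significance level for the power computation.
#' @return An `ef_test_result`.
#' @examples
#' t_test_from_summary(17.6, 0.4, 5, 14.9, 0.9, 5) # p ~ 0.023
#' @export
t_test_from_summary <- function(mean1, sem1, n1, mean2, sem2, n2,
                                paired = FALSE, welch = FALSE, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2, sem1 >= 0, sem2 >= 0)
  s1 <- sem1 * sqrt(n1)
  s2 <- sem2 * sqrt(n2)
  diff <- mean1 - mean2
  if (paired) {
    if (n1 != n2) stop("paired design requires equal group sizes")
    se <- sqrt(sem1^2 + sem2^2)
    df <- n1 - 1
    name <- "paired t-test (from summaries)"
  } else if (welch) {
    se <- sqrt(sem1^2 + sem2^2)
    df <- se^4 / (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
    name <- "Welch t-test (from summaries)"
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    name <- "pooled t-test (from summaries)"
  }
  if (se == 0) {
    if (diff == 0) {
      warning("zero pooled variance with equal means; p = 1 reported")
      return(.test_result(name, 0, df, 1, NA_real_, c(n1, n2),
                          "degenerate: no variance, no effect"))
    }
    stop("zero variance with unequal means: t undefined")
  }
  tval <- diff / se
  p <- 2 * stats::pt(-abs(tval), df)
  tcrit <- stats::qt(1 - alpha / 2, df)
  power <- 1 - stats::pt(tcrit, df, ncp = abs(tval)) +
    stats::pt(-tcrit, df, ncp = abs(tval))
  .test_result(name, tval, df, p, power, c(n1, n2),
               sprintf("difference = %.4g (pooled-SE units: %.3g)", diff, tval))
}

#' One-way ANOVA with Holm-Sidak post-hoc pairs
#'
#' Standard between-groups F (via [stats::aov()]); post-hoc pairwise
#' pooled-MSE t-tests adjusted by the Holm-Sidak step-down procedure.
#' Post-hoc power from the noncentral F at the observed effect
#' (ncp = SS_between / MSE) with alpha = 0.05.
#'
#' @param groups Named list of numeric vectors, each of length `>= 2`.
#' @param alpha Significance level for the power computation.
#' @return An `ef_test_result`; `$posthoc` holds the adjusted pairwise
#'   comparisons.
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2)) stop("each group needs n >= 2")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), ns), levels = names(groups))
  tab <- stats::anova(stats::aov(y ~ g))
  fval <- tab$`F value`[1]
  df1 <- tab$Df[1]
  df2 <- tab$Df[2]
  mse <- tab$`Mean Sq`[2]
  if (!is.finite(fval)) {
    warning("degenerate ANOVA (no within-group variance); p = 1 reported")
    return(.test_result("one-way ANOVA", 0, c(df1, df2), 1, NA_real_, ns,
                        "degenerate: zero residual variance"))
  }
  p <- tab$`Pr(>F)`[1]
  ncp <- tab$`Sum Sq`[1] / mse
  power <- 1 - stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2, ncp = ncp)
  posthoc <- .holm_sidak_pairs(groups, mse, df2)
  .test_result("one-way ANOVA", fval, c(df1, df2), p, power, ns,
               sprintf("grand mean %.4g, MSE %.4g", mean(y), mse), posthoc)
}

# Pairwise pooled-MSE t comparisons with Holm-Sidak step-down adjustment.
.holm_sidak_pairs <- function(groups, mse, df_err) {
  nm <- names(groups)
  pairs <- utils::combn(length(groups), 2)
  raw <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(mse * (1 / length(groups[[i]]) + 1 / length(groups[[j]])))
    tv <- (mean(groups[[i]]) - mean(groups[[j]])) / se
    2 * stats::pt(-abs(tv), df_err)
  })
  m <- length(raw)
  ord <- order(raw)
  adj <- numeric(m)
  adj[ord] <- pmin(1, cummax(1 - (1 - raw[ord])^(m - seq_len(m) + 1)))
  data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
             p_raw = raw, p_adj = adj)
}

#' ANOVA on ranks (Kruskal-Wallis)
#'
#' Wrapper around [stats::kruskal.test()] returning the package's common
#' test-result container. All-tied data are flagged with a warning.
#'
#' @param groups Named list of numeric vectors, each of length `>= 2`.
#' @return An `ef_test_result` (statistic H, df, p; no power).
#' @export
rank_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2)) stop("each group needs n >= 2")
  y <- unlist(groups, use.names = FALSE)
  if (length(unique(y)) == 1) {
    warning("all observations tied; H = 0, p = 1")
    return(.test_result("ANOVA on ranks (Kruskal-Wallis)", 0,
                        length(groups) - 1, 1, NA_real_, ns, "all tied"))
  }
  g <- factor(rep(seq_along(groups), ns))
  kt <- stats::kruskal.test(y, g)
  .test_result("ANOVA on ranks (Kruskal-Wallis)",
               unname(kt$statistic), unname(kt$parameter), kt$p.value,
               NA_real_, ns, "")
}

#' One-way repeated-measures ANOVA
#'
#' Within-subjects F for a complete subjects x timepoints matrix:
#' SS partitioned into subjects, timepoints, and residual;
#' F = MS_time / MS_residual with df (t - 1), (n - 1)(t - 1). Post-hoc power
#' from the noncentral F at the observed effect. Rows with missing cells are
#' dropped listwise.
#'
#' @param mat Numeric matrix, subjects in rows, timepoints in columns
#'   (`>= 2` each after listwise deletion).
#' @param alpha Significance level for the power computation.
#' @return An `ef_test_result`.
#' @export
rm_anova <- function(mat, alpha = 0.05) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) {
    mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  }
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 2 || k < 2) stop("need at least 2 complete subjects and 2 timepoints")
  grand <- mean(mat)
  ss_subj <- k * sum((rowMeans(mat) - grand)^2)
  ss_time <- n * sum((colMeans(mat) - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_res <- ss_tot - ss_subj - ss_time
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  ms_res <- ss_res / df2
  if (ms_res <= 0) {
    if (ss_time == 0) {
      warning("degenerate RM ANOVA: no variance anywhere; p = 1 reported")
      return(.test_result("one-way RM ANOVA", 0, c(df1, df2), 1, NA_real_, n,
                          "degenerate"))
    }
    stop("zero residual variance with a nonzero time effect")
  }
  fval <- (ss_time / df1) / ms_res
  p <- 1 - stats::pf(fval, df1, df2)
  ncp <- ss_time / ms_res
  power <- 1 - stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2, ncp = ncp)
  .test_result("one-way RM ANOVA", fval, c(df1, df2), p, power, n,
               sprintf("%d subjects x %d timepoints", n, k))
}

#' Per-hour cohort comparison
#'
#' One-way ANOVA across cohorts restricted to a single recording hour,
#' using each animal's episode count in that hour.
#'
#' @param cohorts Named list of `data.frame`s of per-animal hourly metrics
#'   (stacked [aggregate_animal()] outputs with `animal_id`).
#' @param hour Hour index (1-based).
#' @param metric Column compared across cohorts (default `episode_count`).
#' @return An `ef_test_result`.
#' @export
per_hour_comparison <- function(cohorts, hour, metric = "episode_count") {
  stopifnot(is.list(cohorts), length(cohorts) >= 2)
  groups <- lapply(cohorts, function(d) {
    x <- d[[metric]][d$hour == hour]
    x[!is.na(x)]
  })
  one_way_anova(groups)
}
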