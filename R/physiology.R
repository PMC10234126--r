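# Physiology arithmetic: hematology conversion and anemia thresholds,
# Hargreaves latency aggregation and normalization, transferrin-receptor
# ratio.

#' Convert hematocrit to hemoglobin
#'
#' The clinical "rule of three": hemoglobin (g/dL) = hematocrit (%) / 3,
#' rounded to one decimal. This transform reproduces both reference
#' hematocrit/hemoglobin pairs used to calibrate the hematology module
#' (52.7% -> 17.6 g/dL, 44.6% -> 14.9 g/dL).
#'
#' @param hct_pct Hematocrit in percent, strictly between 0 and 100.
#' @return Hemoglobin in g/dL, rounded to 1 decimal.
#' @examples
#' hct_to_hb(52.7) # 17.6
#' hct_to_hb(44.6) # 14.9
#' @export
hct_to_hb <- function(hct_pct) {
  if (!is.numeric(hct_pct) || length(hct_pct) != 1 ||
      hct_pct <= 0 || hct_pct >= 100) {
    stop("hct_pct must be a single value strictly between 0 and 100")
  }
  round(hct_pct / 3, 1)
}

#' Anemia classification for mice
#'
#' Mouse anemia cutoffs: hemoglobin below 13.9 g/dL (males) or 13.6 g/dL
#' (females). Boundary equality is not anemic (anemia is defined as values
#' below the cutoff).
#'
#' @param hb_g_dl Hemoglobin in g/dL (`> 0`).
#' @param sex `"M"` or `"F"`.
#' @return Logical: `TRUE` if anemic.
#' @export
is_anemic <- function(hb_g_dl, sex) {
  if (!is.numeric(hb_g_dl) || length(hb_g_dl) != 1 || hb_g_dl <= 0) {
    stop("hb_g_dl must be a single positive value")
  }
  if (!sex %in% c("M", "F")) stop("sex must be 'M' or 'F'")
  cutoff <- if (sex == "M") 13.9 else 13.6
  hb_g_dl < cutoff
}

#' Session latency from Hargreaves trials
#'
#' Arithmetic mean of the session's 5 withdrawal-latency trials.
#'
#' @param trials Numeric vector of exactly 5 latencies in seconds.
#' @return Session mean latency in seconds.
#' @export
session_latency <- function(trials) {
  if (length(trials) != 5) {
    stop("a Hargreaves session has exactly 5 trials, got ", length(trials))
  }
  if (any(trials <= 0)) stop("latencies must be positive")
  mean(trials)
}

#' Per-session means of a latency table
#'
#' Convenience aggregation of [simulate_latency_table()]-shaped data:
#' session (animal x week) means via [session_latency()], then cohort means
#' per week.
#'
#' @param latency_table `data.frame` with `animal_id`, `week`, `latency_s`.
#' @return List with `sessions` (animal x week means) and `weekly` (named
#'   vector of cohort means per week).
#' @export
latency_cohort_means <- function(latency_table) {
  key <- interaction(latency_table$animal_id, latency_table$week, drop = TRUE)
  sess <- do.call(rbind, lapply(split(latency_table, key), function(d) {
    data.frame(animal_id = d$animal_id[1], week = d$week[1],
               session_mean_s = session_latency(d$latency_s))
  }))
  rownames(sess) <- NULL
  weekly <- tapply(sess$session_mean_s, sess$week, mean)
  list(sessions = sess,
       weekly = stats::setNames(as.numeric(weekly), names(weekly)))
}

#' Normalize latency means to a control cohort
#'
#' Expresses per-week cohort means as percent of the same-week control
#' cohort. Week indices must match; control weeks missing for a test week
#' are linearly interpolated (with a warning) when interpolation is
#' possible, otherwise rejected.
#'
#' @param test_means Named numeric vector (names = week indices).
#' @param control_means Named numeric vector (names = week indices),
#'   strictly positive.
#' @return Named numeric vector: 100 * test / control per week.
#' @export
normalize_to_control <- function(test_means, control_means) {
  if (any(control_means <= 0)) stop("control means must be positive")
  tw <- as.numeric(names(test_means))
  cw <- as.numeric(names(control_means))
  if (anyNA(tw) || anyNA(cw)) stop("means must be named by week index")
  ctrl <- control_means[match(tw, cw)]
  missing <- is.na(ctrl)
  if (any(missing)) {
    if (length(cw) < 2 || any(tw[missing] < min(cw)) || any(tw[missing] > max(cw))) {
      stop("week mismatch: control weeks do not cover ",
           paste(tw[missing], collapse = ", "))
    }
    warning("interpolating control means for weeks ",
            paste(tw[missing], collapse = ", "))
    ctrl[missing] <- stats::approx(cw, control_means, xout = tw[missing])$y
  }
  stats::setNames(100 * as.numeric(test_means) / as.numeric(ctrl),
                  names(test_means))
}

#' Recovery ratio relative to an ID-diet baseline
#'
#' Percent change of post-recovery latency means against the same cohort's
#' iron-deficient-diet baseline.
#'
#' @param idr_means Post-recovery mean(s), seconds.
#' @param id_baseline_means Baseline mean(s) under the ID diet, strictly
#'   positive.
#' @return 100 * recovered / baseline (vectorized).
#' @export
recovery_ratio <- function(idr_means, id_baseline_means) {
  if (any(id_baseline_means <= 0)) stop("baseline means must be positive")
  100 * idr_means / id_baseline_means
}

#' Transferrin-receptor expression ratio
#'
#' Band intensity normalized to total protein expression over the entire
#' lane.
#'
#' @param band_intensity Band densitometry intensity (arbitrary units).
#' @param total_lane_intensity Whole-lane intensity, strictly positive.
#' @return Dimensionless ratio band / total.
#' @examples
#' tf_ratio(4.3, 100) # 0.043
#' @export
tf_ratio <- function(band_intensity, total_lane_intensity) {
  if (any(total_lane_intensity <= 0)) {
    stop("total lane intensity must be positive")
  }
  band_intensity / total_lane_intensity
}
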