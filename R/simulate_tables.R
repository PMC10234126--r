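# Tabular physiology generators: Hargreaves latency trials and hematocrit
# samples, calibrated to the cohort presets.

#' Simulate a Hargreaves latency trial table
#'
#' Each animal is tested once per week with exactly 5 trials per session.
#' Trial latencies are log-normal around
#' `latency_baseline * latency_ratio_by_week[w]`, with a per-animal
#' multiplicative random effect held constant across weeks (the same animals
#' are followed longitudinally) and independent trial-level noise. Weekly
#' ratios beyond the preset vector reuse its last entry. Unprinted
#' dispersions default to ~10% trial CV and ~8% animal CV.
#'
#' @param preset A `sim_preset`.
#' @param n_animals Number of animals (`>= 1`).
#' @param n_weeks Number of weekly sessions.
#' @param seed Integer seed.
#' @return `data.frame`: `animal_id`, `week`, `trial` (1-5), `latency_s`.
#' @export
simulate_latency_table <- function(preset, n_animals, n_weeks, seed) {
  stopifnot(inherits(preset, "sim_preset"))
  if (n_animals < 1) stop("n_animals must be at least 1")
  if (n_weeks < 1) stop("n_weeks must be at least 1")
  ratios <- preset$latency_ratio_by_week
  ratios <- ratios[pmin(seq_len(n_weeks), length(ratios))]
  stream <- rng_stream(derive_seed(seed, 7))
  sdl_a <- sqrt(log(1 + preset$latency_animal_cv^2))
  sdl_t <- sqrt(log(1 + preset$latency_trial_cv^2))
  animal_eff <- exp(stream(rnorm, n_animals, -sdl_a^2 / 2, sdl_a))
  rows <- expand.grid(trial = 1:5, week = seq_len(n_weeks),
                      animal = seq_len(n_animals))
  mu <- preset$latency_baseline * ratios[rows$week] * animal_eff[rows$animal]
  lat <- mu * exp(stream(rnorm, nrow(rows), -sdl_t^2 / 2, sdl_t))
  data.frame(animal_id = sprintf("%s_a%02d", preset$group_label, rows$animal),
             week = rows$week, trial = rows$trial,
             latency_s = lat)
}

#' Simulate a hematocrit sample table
#'
#' Gaussian draws at the preset's `(hct_mean, hct_sd)`, truncated to the
#' open interval (0, 100) by resampling, with derived hemoglobin and anemia
#' flags (see [hct_to_hb()] and [is_anemic()]).
#'
#' @param preset A `sim_preset`.
#' @param n Number of animals sampled (`>= 1`).
#' @param seed Integer seed.
#' @param sex Sex recorded per sample; defaults to the preset's, with
#'   `"mixed"` alternating M/F.
#' @return `data.frame`: `animal_id`, `sex`, `hct_pct`, `hb_g_dl`, `anemic`.
#' @export
simulate_hematology <- function(preset, n, seed, sex = NULL) {
  stopifnot(inherits(preset, "sim_preset"))
  if (n < 1) stop("n must be at least 1")
  stream <- rng_stream(derive_seed(seed, 8))
  x <- stream(rnorm, n, preset$hct_mean, preset$hct_sd)
  bad <- which(x <= 0 | x >= 100)
  while (length(bad)) {
    x[bad] <- stream(rnorm, length(bad), preset$hct_mean, preset$hct_sd)
    bad <- which(x <= 0 | x >= 100)
  }
  sex <- sex %||% preset$sex
  sexes <- if (identical(sex, "mixed")) {
    rep(c("M", "F"), length.out = n)
  } else {
    rep(sex, n)
  }
  hb <- vapply(x, hct_to_hb, numeric(1))
  data.frame(animal_id = sprintf("%s_h%02d", preset$group_label, seq_len(n)),
             sex = sexes, hct_pct = x, hb_g_dl = hb,
             anemic = mapply(is_anemic, hb, sexes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
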