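Package: efsleep
Title: Sleep Scoring and Physiology Normalization for Electric-Field
    Sensor Recordings in a Dietary Iron-Deficiency Mouse Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to score rodent sleep from non-invasive capacitive
    electric-field (EF) sensor voltage traces, together with the
    physiological normalizations used alongside such recordings in a
    dietary iron-deficiency model of Restless Legs Syndrome: a calibrated
    semi-Markov simulator of behavioral state sequences and EF traces with
    known ground truth, zero-phase low-pass conditioning, spectrogram and
    breathing-band summaries, robust movement-event detection, the 60-second
    stillness / 1-second twitch sleep-scoring rules with hourly metrics and
    cohort aggregation, hematocrit-to-hemoglobin conversion with anemia
    thresholds, Hargreaves thermal withdrawal latency aggregation and
    normalization, transferrin-receptor ratio arithmetic, and the summary
    statistics (t, one-way/RM/rank ANOVA with post-hoc power) used to
    compare diet cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
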