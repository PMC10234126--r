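# Plain-text interchange: one CSV of volts per session plus a JSON sidecar
# with the acquisition metadata, ground-truth state tracks and detected
# events as tidy CSV. Everything round-trips.

#' Write an EF session to disk
#'
#' Writes `<stem>_trace.csv` (column `volts`), `<stem>_meta.json`
#' (animal_id, sampling_rate, session_date, group) and, when a track is
#' given, `<stem>_truth.csv` (start_s, end_s, state).
#'
#' @param rec An `ef_recording`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem; defaults to the animal id.
#' @param track Optional ground-truth `behavioral_track`.
#' @param group Group label stored in the sidecar.
#' @return Invisibly, the paths written.
#' @export
write_ef_session <- function(rec, dir, stem = rec$animal_id, track = NULL,
                             group = NA_character_) {
  stopifnot(inherits(rec, "ef_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(stem, c("_trace.csv", "_meta.json")))
  utils::write.csv(data.frame(volts = rec$samples), paths[1],
                   row.names = FALSE)
  jsonlite::write_json(
    list(animal_id = rec$animal_id, sampling_rate = rec$sampling_rate,
         session_date = rec$session_date, group = group,
         duration_s = rec$duration_s),
    paths[2], auto_unbox = TRUE, digits = NA)
  if (!is.null(track)) {
    tp <- file.path(dir, paste0(stem, "_truth.csv"))
    utils::write.csv(as.data.frame(track), tp, row.names = FALSE)
    paths <- c(paths, tp)
  }
  invisible(paths)
}

#' Read an EF session written by [write_ef_session()]
#'
#' @param dir Directory holding the session files.
#' @param stem File-name stem.
#' @return An `ef_recording` (with a `group` attribute from the sidecar).
#' @export
read_ef_session <- function(dir, stem) {
  meta <- jsonlite::read_json(file.path(dir, paste0(stem, "_meta.json")),
                              simplifyVector = TRUE)
  volts <- utils::read.csv(file.path(dir, paste0(stem, "_trace.csv")))$volts
  rec <- ef_recording(volts, meta$sampling_rate, meta$animal_id,
                      meta$session_date)
  attr(rec, "group") <- meta$group
  rec
}

#' Export detected movement events as tidy CSV
#'
#' Columns: animal_id, start_s, end_s, duration_s, peak_amplitude,
#' event_class.
#'
#' @param events Event `data.frame` (see [detect_movement_events()]).
#' @param path Output CSV path.
#' @param animal_id Animal identifier column value.
#' @return Invisibly, `path`.
#' @export
write_events_csv <- function(events, path, animal_id = "unknown") {
  out <- cbind(animal_id = rep(animal_id, nrow(events)), events)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
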