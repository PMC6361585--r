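#' Write and read spike tables
#'
#' Columnar spike-time interchange format: one row per spike with columns
#' `unit_id`, `time_s`.
#'
#' @param trains list of [spike_train()] objects.
#' @param path CSV file path.
#' @return `write_spike_table` returns `path` invisibly;
#'   `read_spike_table` returns a list of [spike_train()] objects.
#' @export
write_spike_table <- function(trains, path) {
  df <- do.call(rbind, lapply(trains, function(st)
    data.frame(unit_id = st$unit_id, time_s = st$times)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_table
#' @param session_span session `(start, end)` in seconds for the trains
#'   read back; when `NULL`, inferred as `(0, max spike time)`.
#' @export
read_spike_table <- function(path, session_span = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("unit_id", "time_s") %in% names(df)))
  if (is.null(session_span)) session_span <- c(0, max(df$time_s))
  ids <- unique(df$unit_id)
  lapply(ids, function(id)
    spike_train(id, sort(df$time_s[df$unit_id == id]), session_span))
}

#' Write and read event schedules
#'
#' CSV interchange with columns `label`, `onset_s`, `duration_s`.
#'
#' @param schedule an [event_schedule()].
#' @param path CSV file path.
#' @export
write_event_schedule <- function(schedule, path) {
  utils::write.csv(data.frame(label = schedule$label,
                              onset_s = schedule$onset,
                              duration_s = schedule$duration),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_schedule
#' @export
read_event_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "onset_s", "duration_s") %in% names(df)))
  event_schedule(df$label, df$onset_s, df$duration_s)
}

#' Write and read calcium trace matrices
#'
#' CSV matrix with a `time_s` column followed by one column per cell.
#'
#' @param traces list of [calcium_trace()] objects with equal length and
#'   sample rate.
#' @param path CSV file path.
#' @export
write_calcium_matrix <- function(traces, path) {
  fr <- traces[[1]]$sample_rate
  n <- length(traces[[1]]$dF_F)
  df <- data.frame(time_s = (seq_len(n) - 0.5) / fr)
  for (tr in traces) df[[tr$cell_id]] <- tr$dF_F
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calcium_matrix
#' @param sample_rate sampling rate (Hz) of the stored matrix.
#' @param projection_target,trial_onsets metadata attached to each trace
#'   read back.
#' @export
read_calcium_matrix <- function(path, sample_rate,
                                projection_target = "unknown",
                                trial_onsets = numeric()) {
  df <- utils::read.csv(path, check.names = FALSE)
  cells <- setdiff(names(df), "time_s")
  lapply(cells, function(cl)
    calcium_trace(cl, df[[cl]], sample_rate, projection_target,
                  trial_onsets))
}

#' Write and read occupancy logs
#'
#' CSV interchange for place-test occupancy with columns `chamber`,
#' `start_s`, `end_s`.
#'
#' @param session a [cpp_session()].
#' @param path CSV file path.
#' @export
write_occupancy_log <- function(session, path) {
  occ <- session$occupancy
  utils::write.csv(data.frame(chamber = occ$chamber, start_s = occ$start,
                              end_s = occ$end), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occupancy_log
#' @param phase,photobeam_count,animal_id,group session metadata (not
#'   stored in the occupancy CSV).
#' @export
read_occupancy_log <- function(path, phase = "pre", photobeam_count = 0L,
                               animal_id = "a1", group = "sham") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chamber", "start_s", "end_s") %in% names(df)))
  cpp_session(data.frame(chamber = df$chamber, start = df$start_s,
                         end = df$end_s),
              phase = phase, photobeam_count = photobeam_count,
              animal_id = animal_id, group = group)
}
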