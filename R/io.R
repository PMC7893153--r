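#' Write / read two-channel traces as CSV
#'
#' Long format, one row per frame: `fly_id`, `neuron_class`, `trial_index`,
#' `t_s`, `G`, `T`. A list of traces is concatenated. The frame rate is
#' recoverable from the time grid; ground-truth amplitude attributes are not
#' serialised (they are simulation bookkeeping, not data).
#'
#' @param traces A `two_channel_trace` or list of them.
#' @param path CSV path.
#' @export
write_trace_csv <- function(traces, path) {
  if (is.data.frame(traces)) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, as.data.frame))
  utils::write.csv(df[, c("fly_id", "neuron_class", "trial_index", "t_s", "G", "T")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @return `read_trace_csv` returns one long data frame of frames.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("fly_id", "neuron_class", "trial_index", "t_s", "G", "T")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("trace CSV is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write / read a trial schedule as JSON
#'
#' Serialises the trial records together with the frame-rate and window
#' constants, so a schedule round-trips losslessly.
#'
#' @param schedule A `trial_schedule`.
#' @param path JSON path.
#' @export
write_schedule_json <- function(schedule, path) {
  obj <- list(frame_rate = attr(schedule, "frame_rate"),
              trial_duration = attr(schedule, "trial_duration"),
              imaging_window = attr(schedule, "imaging_window"),
              trials = as.data.frame(schedule))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_schedule_json
#' @return `read_schedule_json` returns a `trial_schedule`.
#' @export
read_schedule_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sched <- as.data.frame(obj$trials, stringsAsFactors = FALSE)
  sched$shock_onset <- as.numeric(sched$shock_onset)
  sched$shock_duration <- as.numeric(sched$shock_duration)
  out <- structure(sched, frame_rate = obj$frame_rate,
                   trial_duration = obj$trial_duration,
                   imaging_window = obj$imaging_window,
                   class = c("trial_schedule", "data.frame"))
  validate_trial_schedule(out)
  out
}

#' Write / read quadrant count tables as CSV
#'
#' Columns `config_id` plus either `n_csplus`/`n_csminus` (conditioning
#' assay) or `n_light`/`n_dark` (innate light-preference assay).
#'
#' @param counts Data frame of counts.
#' @param path CSV path.
#' @export
write_quadrant_counts <- function(counts, path) {
  utils::write.csv(counts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_quadrant_counts
#' @export
read_quadrant_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ok <- all(c("n_csplus", "n_csminus") %in% names(df)) ||
    all(c("n_light", "n_dark") %in% names(df))
  if (!ok) stop("counts CSV needs n_csplus/n_csminus or n_light/n_dark columns")
  df
}

#' Write a response table as CSV
#'
#' @param responses Response table from [process_experiment()].
#' @param path CSV path.
#' @export
write_response_csv <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_response_csv
#' @export
read_response_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("fly_id", "trial_index", "phase", "odor", "mean_odor_response")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("response CSV is missing column(s): ", paste(miss, collapse = ", "))
  df
}
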