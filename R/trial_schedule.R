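#' Generate a conditioning trial schedule
#'
#' Builds the trial-by-trial protocol of an olfactory classical-conditioning
#' experiment with an acquisition phase followed by an optional reversal
#' phase. Trials alternate CS+ / CS-. During acquisition every CS+ trial is
#' paired with an electric shock; during reversal the contingency flips and
#' the shock accompanies CS- instead. Mock protocols keep the identical trial
#' structure but deliver no shock at all.
#'
#' Timing follows the imaging protocol: each trial lasts `trial_duration`
#' seconds but only the first `imaging_window` seconds are recorded; the
#' odor arrives `odor_onset` seconds after imaging onset for `odor_duration`
#' seconds, and on shock trials the shock starts 4 s after odor onset and
#' lasts 100 ms.
#'
#' @param n_acquisition Number of acquisition trials per odor (>= 1).
#' @param n_reversal Number of reversal trials per odor (>= 0).
#' @param mock If `TRUE`, no trial carries a shock and phases are labelled
#'   `mock_acquisition` / `mock_reversal`.
#' @param frame_rate Imaging frame rate in frames/s.
#' @param trial_duration Full trial length in seconds.
#' @param imaging_window Recorded (illuminated) span at the start of each
#'   trial, in seconds.
#' @param odor_onset Odor onset in seconds, relative to imaging onset.
#' @param odor_duration Odor pulse length in seconds.
#'
#' @return A data frame of class `trial_schedule` with one row per trial and
#'   columns `index`, `phase`, `odor`, `odor_onset`, `odor_duration`,
#'   `shock`, `shock_onset` (seconds relative to odor onset) and
#'   `shock_duration`. Frame rate and window constants are carried as
#'   attributes.
#' @examples
#' sched <- generate_trial_schedule(5, 2)
#' table(sched$phase, sched$shock)
#' @export
generate_trial_schedule <- function(n_acquisition, n_reversal, mock = FALSE,
                                    frame_rate = 5, trial_duration = 60,
                                    imaging_window = 20,
                                    odor_onset = 5, odor_duration = 5) {
  if (n_acquisition < 1 || n_reversal < 0) {
    stop("invalid protocol: need n_acquisition >= 1 and n_reversal >= 0")
  }
  if (odor_onset + odor_duration > imaging_window) {
    stop("invalid protocol: odor pulse must end within the imaging window")
  }
  phase_acq <- if (mock) "mock_acquisition" else "acquisition"
  phase_rev <- if (mock) "mock_reversal" else "reversal"
  phase <- c(rep(phase_acq, 2L * n_acquisition), rep(phase_rev, 2L * n_reversal))
  n_trials <- length(phase)
  odor <- rep(c("CSplus", "CSminus"), length.out = n_trials)
  # acquisition: shock with CS+; reversal: shock with CS-
  shock <- !mock & ((phase == phase_acq & odor == "CSplus" & !mock) |
                      (phase == phase_rev & odor == "CSminus"))
  sched <- data.frame(
    index = seq_len(n_trials),
    phase = phase,
    odor = odor,
    odor_onset = odor_onset,
    odor_duration = odor_duration,
    shock = shock,
    shock_onset = ifelse(shock, 4.0, NA_real_),
    shock_duration = ifelse(shock, 0.1, NA_real_),
    stringsAsFactors = FALSE
  )
  structure(sched,
            frame_rate = frame_rate,
            trial_duration = trial_duration,
            imaging_window = imaging_window,
            class = c("trial_schedule", "data.frame"))
}

#' Validate a trial schedule
#'
#' Checks the structural invariants a schedule must satisfy before it can be
#' simulated from or analysed against: strictly increasing trial indices,
#' odor pulses contained in the imaging window, shocks only after odor onset
#' and never on mock trials.
#'
#' @param schedule A `trial_schedule` (or equivalent data frame with the same
#'   columns and attributes).
#' @return The schedule, invisibly; errors describe the first violation.
#' @export
validate_trial_schedule <- function(schedule) {
  req <- c("index", "phase", "odor", "odor_onset", "odor_duration",
           "shock", "shock_onset", "shock_duration")
  miss <- setdiff(req, names(schedule))
  if (length(miss)) stop("schedule is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(schedule) == 0L) stop("schedule has no trials")
  if (any(diff(schedule$index) <= 0)) stop("trial indices must be strictly increasing")
  win <- attr(schedule, "imaging_window") %||% 20
  if (any(schedule$odor_onset + schedule$odor_duration > win)) {
    stop("odor pulse extends beyond the imaging window")
  }
  if (any(schedule$shock & grepl("^mock", schedule$phase))) {
    stop("mock trials cannot carry a shock")
  }
  sh <- schedule[schedule$shock, , drop = FALSE]
  if (nrow(sh) && any(sh$shock_onset < 0)) {
    stop("shock cannot precede odor onset")
  }
  invisible(schedule)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Frame times of one imaging segment
#'
#' @param schedule A `trial_schedule`.
#' @return Numeric vector of within-trial frame times (s), a uniform grid at
#'   the schedule's frame rate covering `[0, imaging_window)`.
#' @keywords internal
trial_frame_times <- function(schedule) {
  fr <- attr(schedule, "frame_rate") %||% 5
  win <- attr(schedule, "imaging_window") %||% 20
  seq(0, win - 1 / fr, by = 1 / fr)
}
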