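#' Ratiometric fluorescence signal
#'
#' Divides the activity channel by the reference channel frame by frame.
#' Because a movement artifact multiplies both channels identically, it
#' cancels exactly in this ratio; that is the entire point of co-expressing
#' a calcium-insensitive reference fluorophore.
#'
#' @param G,T Numeric vectors of equal length; `T` must be strictly positive.
#' @return Numeric vector `G/T`.
#' @export
compute_ratio <- function(G, T) {
  if (length(G) != length(T)) stop("channel lengths differ")
  bad <- which(T <= 0)
  if (length(bad)) {
    stop("degenerate reference channel: T <= 0 at frame ", bad[1])
  }
  G / T
}

#' Fit a double-exponential trend
#'
#' Least-squares fit of `f(t) = a1*exp(-t/tau1) + a2*exp(-t/tau2) + c`.
#' Deterministic multi-start: for every ordered pair of time constants from
#' `tau_grid` the linear coefficients `(a1, a2, c)` are solved exactly
#' (variable projection), and the best grid candidate is refined by bounded
#' Levenberg-Marquardt. No randomness is involved.
#'
#' @param y Response values.
#' @param t Times (s), same length as `y`.
#' @param tau_grid Candidate time constants (s) for the multi-start.
#' @return A list with `par` (named vector `a1, tau1, a2, tau2, c`, with
#'   `tau1 <= tau2`), `fitted`, `rss`, and `converged`.
#' @export
fit_double_exponential <- function(y, t, tau_grid = c(5, 30, 100, 300)) {
  stopifnot(length(y) == length(t), length(y) >= 5)
  proj <- function(tau1, tau2) {
    X <- cbind(exp(-t / tau1), exp(-t / tau2), 1)
    fit <- stats::lm.fit(X, y)
    list(par = c(a1 = fit$coefficients[[1]], tau1 = tau1,
                 a2 = fit$coefficients[[2]], tau2 = tau2,
                 c = fit$coefficients[[3]]),
         rss = sum(fit$residuals^2))
  }
  pairs <- utils::combn(sort(tau_grid), 2)
  cands <- lapply(seq_len(ncol(pairs)), function(j) proj(pairs[1, j], pairs[2, j]))
  best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "rss"))]]
  start <- best$par
  start[is.na(start)] <- 0
  tmax <- max(t) - min(t)
  resid_fn <- function(p) {
    y - (p[1] * exp(-t / p[2]) + p[3] * exp(-t / p[4]) + p[5])
  }
  jac_fn <- function(p) {
    e1 <- exp(-t / p[2]); e2 <- exp(-t / p[4])
    -cbind(e1, p[1] * e1 * t / p[2]^2, e2, p[3] * e2 * t / p[4]^2, 1)
  }
  # flat or single-exponential profiles leave the taus unidentified and LM
  # may hit maxiter wandering a flat RSS valley; the rss guard below keeps
  # the result at least as good as the grid start, so that is harmless
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = unname(start), fn = resid_fn, jac = jac_fn,
      lower = c(-Inf, 1e-2, -Inf, 1e-2, -Inf),
      upper = c(Inf, 500 * tmax, Inf, 500 * tmax, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit)) {
    par <- best$par
    fitted <- par[["a1"]] * exp(-t / par[["tau1"]]) +
      par[["a2"]] * exp(-t / par[["tau2"]]) + par[["c"]]
    return(list(par = par, fitted = fitted, rss = best$rss, converged = TRUE))
  }
  par <- stats::setNames(fit$par, c("a1", "tau1", "a2", "tau2", "c"))
  if (par[["tau1"]] > par[["tau2"]]) {  # canonical order: fast term first
    par <- par[c("a2", "tau2", "a1", "tau1", "c")]
    names(par) <- c("a1", "tau1", "a2", "tau2", "c")
  }
  fitted <- par[["a1"]] * exp(-t / par[["tau1"]]) +
    par[["a2"]] * exp(-t / par[["tau2"]]) + par[["c"]]
  rss <- sum((y - fitted)^2)
  if (rss > best$rss) {  # refinement must not lose to its own start
    par <- best$par
    fitted <- par[["a1"]] * exp(-t / par[["tau1"]]) +
      par[["a2"]] * exp(-t / par[["tau2"]]) + par[["c"]]
    rss <- best$rss
  }
  list(par = par, fitted = fitted, rss = rss, converged = TRUE)
}

#' Photobleaching correction of a ratio trace
#'
#' Fits the double-exponential trend to the frames outside `stimulus_mask`
#' (so evoked transients do not bias the trend) and subtracts it, adding the
#' fitted value at the first frame back so the initial signal level is
#' preserved: `R_detrended(t) = R(t) - f(t) + f(t0)`. If the nonlinear fit
#' fails the trend falls back to a straight line and `fit_ok` is `FALSE`.
#'
#' @param ratio Ratio trace.
#' @param t Frame times (s).
#' @param stimulus_mask Logical vector marking frames to exclude from the
#'   trend fit (stimulus-evoked activity), or `NULL` for none.
#' @return A list with `R_detrended`, `fit_params`, `fit_ok`.
#' @export
detrend_bleach <- function(ratio, t, stimulus_mask = NULL) {
  stopifnot(length(ratio) == length(t))
  if (is.null(stimulus_mask)) stimulus_mask <- rep(FALSE, length(t))
  keep <- !stimulus_mask
  if (!any(keep)) stop("insufficient baseline: all frames are masked")
  if (sum(keep) < 20) stop("insufficient baseline: need >= 20 unmasked frames")
  fit <- tryCatch(fit_double_exponential(ratio[keep], t[keep]),
                  error = function(e) NULL)
  if (!is.null(fit) && fit$converged && all(is.finite(fit$par))) {
    f <- fit$par[["a1"]] * exp(-t / fit$par[["tau1"]]) +
      fit$par[["a2"]] * exp(-t / fit$par[["tau2"]]) + fit$par[["c"]]
    return(list(R_detrended = ratio - f + f[1], fit_params = fit$par, fit_ok = TRUE))
  }
  lin <- stats::lm.fit(cbind(1, t[keep]), ratio[keep])$coefficients
  f <- lin[1] + lin[2] * t
  list(R_detrended = ratio - f + f[1],
       fit_params = c(a1 = 0, tau1 = NA_real_, a2 = 0, tau2 = NA_real_, c = lin[[1]]),
       fit_ok = FALSE)
}

#' Baseline-normalised signal change
#'
#' Converts a detrended ratio trace to dR/R0 with the baseline `R0` defined
#' as the mean over the first `baseline_window` seconds of the recording
#' (before odor onset); the window is half-open, so at 5 frames/s a 5-s
#' baseline uses exactly 25 frames.
#'
#' @param R_detrended Detrended ratio trace.
#' @param t Frame times (s), starting at 0 at imaging onset.
#' @param baseline_window Baseline span (s).
#' @return A list with `dRR` and `R0`.
#' @export
compute_dff <- function(R_detrended, t, baseline_window = 5) {
  stopifnot(length(R_detrended) == length(t))
  if (max(t) < baseline_window) stop("trace shorter than the baseline window")
  in_base <- t >= 0 & t < baseline_window
  R0 <- mean(R_detrended[in_base])
  if (!is.finite(R0) || R0 <= 0) stop("non-positive baseline R0")
  list(dRR = (R_detrended - R0) / R0, R0 = R0)
}

window_mean <- function(x, t, start, end, what) {
  dt <- if (length(t) > 1) t[2] - t[1] else 0
  inside <- t >= start & t < end
  if (!any(inside)) stop("truncated window: no frames in [", start, ", ", end, ") for ", what)
  # trace must cover the full half-open window
  if (min(t) > start + 1e-9 || max(t) + dt < end - 1e-9) {
    stop("truncated window: trace does not cover [", start, ", ", end, ") s (", what, ")")
  }
  mean(x[inside])
}

#' Mean odor response
#'
#' Mean dR/R0 over the first 4 s after odor onset (half-open window, 20
#' frames at 5 fps). The window deliberately stops at +4 s so it cannot be
#' confounded by a shock response, which on paired trials starts exactly 4 s
#' after odor onset.
#'
#' @param dRR dR/R0 trace.
#' @param t Frame times (s).
#' @param odor_onset Odor onset (s).
#' @param window Response window length (s).
#' @return Scalar mean response.
#' @export
mean_odor_response <- function(dRR, t, odor_onset, window = 4) {
  window_mean(dRR, t, odor_onset, odor_onset + window, "odor response")
}

#' Mean shock response
#'
#' Mean dR/R0 over the 800 ms after shock onset (4 frames at 5 fps). The
#' window ends before odor offset at onset + 5 s so an odor-offset transient
#' cannot leak in.
#'
#' @param dRR dR/R0 trace.
#' @param t Frame times (s).
#' @param odor_onset Odor onset (s); the shock starts 4 s later.
#' @param shock Logical; must be `TRUE` (calling this on a no-shock trial is
#'   a contract error, the metric is undefined there).
#' @return Scalar mean response.
#' @export
mean_shock_response <- function(dRR, t, odor_onset, shock = TRUE) {
  if (!isTRUE(shock)) stop("mean_shock_response called on a trial without shock")
  window_mean(dRR, t, odor_onset + 4.0, odor_onset + 4.8, "shock response")
}

#' Process one imaging trial
#'
#' ratio -> bleach detrend (stimulus frames masked) -> dR/R0 -> windowed
#' response metrics, for a single trial segment.
#'
#' @param G,T Channel vectors for the trial.
#' @param t Within-trial frame times (s), 0 at imaging onset.
#' @param trial One row of a [generate_trial_schedule()].
#' @param mask_pad Seconds past odor offset still masked during the trend
#'   fit, covering transient decay.
#' @return A list with `dRR`, `R0`, `fit_ok`, `mean_odor_response`,
#'   `mean_shock_response` (`NA` on no-shock trials).
#' @export
process_trial <- function(G, T, t, trial, mask_pad = 3) {
  ratio <- compute_ratio(G, T)
  mask <- t >= trial$odor_onset &
    t < trial$odor_onset + trial$odor_duration + mask_pad
  det <- detrend_bleach(ratio, t, mask)
  dff <- compute_dff(det$R_detrended, t)
  list(dRR = dff$dRR, R0 = dff$R0, fit_ok = det$fit_ok,
       mean_odor_response = mean_odor_response(dff$dRR, t, trial$odor_onset),
       mean_shock_response = if (isTRUE(trial$shock)) {
         mean_shock_response(dff$dRR, t, trial$odor_onset)
       } else NA_real_)
}

#' Process a set of traces against a schedule
#'
#' Applies [process_trial()] to every (fly, trial) segment. Each 20-s
#' imaging segment is detrended independently, because illumination (and so
#' photobleaching) is interrupted between trials and the baseline is defined
#' per recording.
#'
#' @param traces A single `two_channel_trace`, a list of them, or a long
#'   data frame with columns `fly_id`, `neuron_class`, `trial_index`, `t_s`,
#'   `G`, `T`.
#' @param schedule The trial schedule the traces were recorded under.
#' @return A response table: one row per (fly, trial) with columns `fly_id`,
#'   `neuron_class`, `trial_index`, `phase`, `odor`, `mean_odor_response`,
#'   `mean_shock_response` (`NA` where no shock was delivered) and `fit_ok`.
#' @export
process_experiment <- function(traces, schedule) {
  validate_trial_schedule(schedule)
  if (is.data.frame(traces)) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, as.data.frame))
  if (is.null(df) || nrow(df) == 0L) {
    return(data.frame(fly_id = character(), neuron_class = character(),
                      trial_index = integer(), phase = character(),
                      odor = character(), mean_odor_response = numeric(),
                      mean_shock_response = numeric(), fit_ok = logical(),
                      stringsAsFactors = FALSE))
  }
  if (!all(unique(df$trial_index) %in% schedule$index)) {
    stop("trace contains trial indices absent from the schedule")
  }
  out <- list()
  for (fly in unique(df$fly_id)) {
    dfly <- df[df$fly_id == fly, , drop = FALSE]
    for (ti in sort(unique(dfly$trial_index))) {
      seg <- dfly[dfly$trial_index == ti, , drop = FALSE]
      seg <- seg[order(seg$t_s), , drop = FALSE]
      trial <- schedule[schedule$index == ti, , drop = FALSE]
      res <- tryCatch(
        process_trial(seg$G, seg$T, seg$t_s, trial),
        error = function(e) stop("fly ", fly, ", trial ", ti, ": ",
                                 conditionMessage(e), call. = FALSE))
      out[[length(out) + 1L]] <- data.frame(
        fly_id = fly, neuron_class = seg$neuron_class[1],
        trial_index = ti, phase = trial$phase, odor = trial$odor,
        mean_odor_response = res$mean_odor_response,
        mean_shock_response = res$mean_shock_response,
        fit_ok = res$fit_ok, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
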