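#' Simulation configuration for two-channel traces
#'
#' Bundles the generative parameters of the synthetic imaging model. The
#' activity channel (GCaMP) is built as
#' `G(t) = [baseline_G + sum_events amp * k(t - onset)] * B_G(t) * M(t) + eps_G`
#' and the reference channel (tdTomato) as
#' `T(t) = baseline_T * B_T(t) * M(t) + eps_T`, where `B` is a
#' double-exponential photobleaching factor, `M` a multiplicative motion
#' artifact shared identically by both channels (so that it cancels in the
#' ratio), `k` a difference-of-exponentials transient kernel normalised to
#' unit peak, and `eps` white Gaussian read noise.
#'
#' @param bleach_G,bleach_T Named vectors `(a1, tau1, a2, tau2, c)` of the
#'   per-channel bleaching factor `a1*exp(-t/tau1) + a2*exp(-t/tau2) + c`,
#'   evaluated in cumulative illumination time (taus in seconds). Defaults
#'   are shared across channels.
#' @param baseline_G,baseline_T Channel baselines in arbitrary fluorescence
#'   units; `baseline_T` must be positive.
#' @param motion_sd Log-scale standard deviation of the shared multiplicative
#'   motion artifact (0 disables it).
#' @param noise_sd Per-channel additive noise standard deviation (a.u.).
#' @param kernel_rise,kernel_decay Rise and decay time constants (s) of the
#'   calcium transient kernel.
#' @param odor_amp Peak amplitude (a.u.) of an odor-evoked transient at
#'   plasticity multiplier 1.
#' @param shock_response_amp Peak amplitude (a.u.) of a shock-evoked
#'   transient.
#' @param fly_amp_cv Between-fly coefficient of variation of a lognormal
#'   response gain applied to all of a fly's transients (0 disables it).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(bleach_G = c(a1 = 0.3, tau1 = 30, a2 = 0.1, tau2 = 300, c = 0.6),
                       bleach_T = bleach_G,
                       baseline_G = 100, baseline_T = 100,
                       motion_sd = 0.05, noise_sd = 1.0,
                       kernel_rise = 0.2, kernel_decay = 1.5,
                       odor_amp = 40, shock_response_amp = 30,
                       fly_amp_cv = 0.25) {
  for (b in list(bleach_G, bleach_T)) {
    stopifnot(all(c("a1", "tau1", "a2", "tau2", "c") %in% names(b)))
    if (b[["tau1"]] <= 0 || b[["tau2"]] <= 0) stop("bleach taus must be positive")
  }
  if (baseline_T <= 0) stop("invalid config: reference baseline must be positive")
  if (kernel_rise <= 0 || kernel_decay <= 0 || kernel_rise >= kernel_decay) {
    stop("kernel requires 0 < rise < decay")
  }
  if (odor_amp < 0 || shock_response_amp < 0) stop("amplitudes must be >= 0")
  if (motion_sd < 0 || noise_sd < 0 || fly_amp_cv < 0) stop("spreads must be >= 0")
  structure(list(bleach_G = bleach_G, bleach_T = bleach_T,
                 baseline_G = baseline_G, baseline_T = baseline_T,
                 motion_sd = motion_sd, noise_sd = noise_sd,
                 kernel_rise = kernel_rise, kernel_decay = kernel_decay,
                 odor_amp = odor_amp, shock_response_amp = shock_response_amp,
                 fly_amp_cv = fly_amp_cv),
            class = "sim_config")
}

#' Per-trial response-amplitude multipliers for a neuron class
#'
#' Declarative plasticity profiles: for each odor, one multiplier per trial
#' of that odor (acquisition trials first, then reversal trials), applied to
#' the configured base odor amplitude. The `"pam_b2a"` preset mimics a
#' reward-signalling dopaminergic class whose CS+ odor response falls to half
#' its naive value across five acquisition trials and climbs back across the
#' two reversal trials once the shock is omitted, while the CS- response is
#' stable. `"flat"` keeps every multiplier at 1 (mock conditioning).
#'
#' @param preset `"pam_b2a"` or `"flat"`.
#' @param n_acquisition,n_reversal Trials per odor in each phase.
#' @return A list with numeric vectors `CSplus` and `CSminus` of length
#'   `n_acquisition + n_reversal`.
#' @export
plasticity_preset <- function(preset = c("pam_b2a", "flat"),
                              n_acquisition = 5, n_reversal = 2) {
  preset <- match.arg(preset)
  n <- n_acquisition + n_reversal
  flat <- rep(1, n)
  if (preset == "flat") return(list(CSplus = flat, CSminus = flat))
  acq <- seq(1.0, 0.5, length.out = n_acquisition)
  rev <- if (n_reversal > 0) seq(0.65, 0.90, length.out = max(n_reversal, 2L))[seq_len(n_reversal)] else numeric()
  list(CSplus = c(acq, rev), CSminus = flat)
}

# difference-of-exponentials transient, unit peak, causal
transient_kernel <- function(t, rise, decay) {
  tpk <- log(decay / rise) * rise * decay / (decay - rise)
  peak <- exp(-tpk / decay) - exp(-tpk / rise)
  k <- ifelse(t >= 0, (exp(-t / decay) - exp(-t / rise)) / peak, 0)
  k
}

double_exp <- function(t, p) {
  p[["a1"]] * exp(-t / p[["tau1"]]) + p[["a2"]] * exp(-t / p[["tau2"]]) + p[["c"]]
}

# low-pass-filtered multiplicative lognormal motion artifact, unit median
motion_path <- function(n, sd, frame_rate) {
  if (sd == 0) return(rep(1, n))
  width <- max(1L, as.integer(round(frame_rate)))  # ~1 s smoothing
  z <- stats::rnorm(n + 2L * width)
  sm <- stats::filter(z, rep(1 / width, width), sides = 2)
  sm <- sm[width + seq_len(n)]
  exp(sd * sm * sqrt(width))  # rescaled to unit log-sd
}

#' Simulate a two-channel fluorescence trace
#'
#' Generates the activity and reference channels of one ROI across every
#' trial of a schedule, per the generative model in [sim_config()]. Each
#' trial contributes one `imaging_window`-second segment sampled at the
#' schedule's frame rate; photobleaching progresses with cumulative
#' illumination time across trials, whereas time `t_s` restarts at 0 within
#' each trial (illumination is off between imaging windows).
#'
#' The true (post fly-gain) transient amplitudes of every trial are attached
#' as attribute `true_amplitudes` so recovery can be tested against ground
#' truth.
#'
#' @param config A [sim_config()].
#' @param schedule A [generate_trial_schedule()] result.
#' @param neuron_class Label used to pick the plasticity profile rows.
#' @param fly_id Identifier stored with the trace.
#' @param plasticity Profile as returned by [plasticity_preset()]; defaults
#'   to the flat profile.
#' @param seed Integer seed; the trace is bitwise reproducible given the
#'   seed (the global RNG state is left untouched).
#' @return A data frame of class `two_channel_trace` with columns `fly_id`,
#'   `neuron_class`, `trial_index`, `t_s`, `G`, `T` and attributes
#'   `frame_rate` and `true_amplitudes`.
#' @export
simulate_trace <- function(config, schedule, neuron_class = "generic",
                           fly_id = "fly1", plasticity = NULL, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  validate_trial_schedule(schedule)
  fr <- attr(schedule, "frame_rate") %||% 5
  tt <- trial_frame_times(schedule)
  nfr <- length(tt)
  win <- attr(schedule, "imaging_window") %||% 20
  n_trials <- nrow(schedule)
  if (is.null(plasticity)) {
    per_odor <- table(schedule$odor)
    nmax <- max(per_odor)
    plasticity <- list(CSplus = rep(1, nmax), CSminus = rep(1, nmax))
  }

  withr::with_seed(seed, {
    gain <- if (config$fly_amp_cv > 0) {
      sdl <- sqrt(log(1 + config$fly_amp_cv^2))
      stats::rlnorm(1, meanlog = -sdl^2 / 2, sdlog = sdl)
    } else 1
    G <- T_ <- numeric(n_trials * nfr)
    trial_index <- rep(schedule$index, each = nfr)
    odor_rank <- stats::ave(seq_len(n_trials), schedule$odor, FUN = seq_along)
    truth <- data.frame(trial_index = schedule$index, phase = schedule$phase,
                        odor = schedule$odor,
                        odor_amp = NA_real_, shock_amp = NA_real_)
    for (i in seq_len(n_trials)) {
      tr <- schedule[i, ]
      mult <- plasticity[[tr$odor]][odor_rank[i]]
      if (is.na(mult)) stop("plasticity profile too short for trial ", tr$index)
      amp <- gain * config$odor_amp * mult
      clean <- config$baseline_G +
        amp * transient_kernel(tt - tr$odor_onset, config$kernel_rise, config$kernel_decay)
      shock_amp <- 0
      if (isTRUE(tr$shock)) {
        shock_amp <- gain * config$shock_response_amp
        clean <- clean + shock_amp *
          transient_kernel(tt - (tr$odor_onset + tr$shock_onset),
                           config$kernel_rise, config$kernel_decay)
      }
      t_exp <- (i - 1) * win + tt  # cumulative illumination time
      bG <- double_exp(t_exp, config$bleach_G)
      bT <- double_exp(t_exp, config$bleach_T)
      M <- motion_path(nfr, config$motion_sd, fr)
      idx <- (i - 1) * nfr + seq_len(nfr)
      G[idx] <- clean * bG * M + stats::rnorm(nfr, 0, config$noise_sd)
      T_[idx] <- config$baseline_T * bT * M + stats::rnorm(nfr, 0, config$noise_sd)
      truth$odor_amp[i] <- amp
      truth$shock_amp[i] <- if (isTRUE(tr$shock)) shock_amp else NA_real_
    }
    out <- data.frame(fly_id = fly_id, neuron_class = neuron_class,
                      trial_index = trial_index,
                      t_s = rep(tt, n_trials), G = G, T = T_,
                      stringsAsFactors = FALSE)
    structure(out, frame_rate = fr, true_amplitudes = truth,
              class = c("two_channel_trace", "data.frame"))
  })
}

#' Simulate a cohort of flies
#'
#' Convenience wrapper running [simulate_trace()] once per fly with
#' fly-specific seeds derived deterministically from `seed`.
#'
#' @inheritParams simulate_trace
#' @param n_flies Number of flies.
#' @return A list of `two_channel_trace` objects named by fly id.
#' @export
simulate_experiment <- function(config, schedule, n_flies,
                                neuron_class = "generic",
                                plasticity = NULL, seed = 1L) {
  stopifnot(n_flies >= 1)
  lapply(stats::setNames(seq_len(n_flies),
                         sprintf("fly%02d", seq_len(n_flies))), function(i) {
    simulate_trace(config, schedule, neuron_class = neuron_class,
                   fly_id = sprintf("fly%02d", i), plasticity = plasticity,
                   seed = (seed * 1009L + i) %% .Machine$integer.max)
  })
}

#' Simulate quadrant-arena occupancy counts
#'
#' Draws the number of flies found in CS- quadrants at test time from a
#' binomial model: each of `n_flies` independently sits in a CS- quadrant
#' with probability `p_csminus`, the rest are in CS+ quadrants.
#'
#' @param p_csminus Probability a fly occupies a CS- quadrant.
#' @param n_flies Number of flies in the arena (>= 1).
#' @param seed Integer seed.
#' @param config_id Label for the quadrant arrangement.
#' @return A one-row data frame with columns `config_id`, `n_csplus`,
#'   `n_csminus`.
#' @export
simulate_quadrant_counts <- function(p_csminus, n_flies, seed = 1L,
                                     config_id = "cfg1") {
  if (p_csminus < 0 || p_csminus > 1) stop("p_csminus must be in [0, 1]")
  if (n_flies < 1) stop("n_flies must be >= 1")
  withr::with_seed(seed, {
    n_minus <- stats::rbinom(1, n_flies, p_csminus)
    data.frame(config_id = config_id,
               n_csplus = n_flies - n_minus, n_csminus = n_minus,
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic synapse table
#'
#' Emits a neuPrint-export-style table with one row per synaptic contact for
#' each requested (presynaptic type, postsynaptic type) block. Per-pair
#' contact counts are drawn from a Poisson distribution with the block's
#' `mean_count`, or fixed exactly via `exact_counts`. Synapse coordinates are
#' uniform in the unit box; the tracing-status flags default to fully traced.
#'
#' @param blocks A data frame (or list of lists) with columns/fields
#'   `pre_type`, `post_type`, `n_pre_cells`, `n_post_cells`, `mean_count`,
#'   `roi`.
#' @param seed Integer seed.
#' @param exact_counts Optional list, parallel to the rows of `blocks`, each
#'   entry either `NULL` (Poisson draw) or an `n_pre_cells x n_post_cells`
#'   matrix of exact per-pair counts.
#' @return A data frame of class `synapse_table` with columns `pre_id`,
#'   `pre_type`, `post_id`, `post_type`, `roi`, `x`, `y`, `z`, `pre_traced`,
#'   `post_traced`. Attribute `true_counts` keeps the per-pair ground truth.
#' @export
generate_synapse_table <- function(blocks, seed = 1L, exact_counts = NULL) {
  if (!is.data.frame(blocks)) blocks <- do.call(rbind, lapply(blocks, as.data.frame))
  if (any(blocks$mean_count < 0)) stop("mean_count must be >= 0")
  withr::with_seed(seed, {
    rows <- list()
    truth <- list()
    for (b in seq_len(nrow(blocks))) {
      blk <- blocks[b, ]
      pre_ids <- sprintf("%s_%03d", blk$pre_type, seq_len(blk$n_pre_cells))
      post_ids <- sprintf("%s_%03d", blk$post_type, seq_len(blk$n_post_cells))
      cnt <- if (!is.null(exact_counts) && !is.null(exact_counts[[b]])) {
        m <- exact_counts[[b]]
        stopifnot(nrow(m) == blk$n_pre_cells, ncol(m) == blk$n_post_cells)
        m
      } else {
        matrix(stats::rpois(blk$n_pre_cells * blk$n_post_cells, blk$mean_count),
               nrow = blk$n_pre_cells)
      }
      n_syn <- sum(cnt)
      truth[[b]] <- data.frame(pre_type = blk$pre_type, post_type = blk$post_type,
                               pre_id = pre_ids[row(cnt)], post_id = post_ids[col(cnt)],
                               count = as.vector(cnt), stringsAsFactors = FALSE)
      if (n_syn == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        pre_id = rep(pre_ids[row(cnt)], as.vector(cnt)),
        pre_type = blk$pre_type,
        post_id = rep(post_ids[col(cnt)], as.vector(cnt)),
        post_type = blk$post_type,
        roi = blk$roi,
        x = stats::runif(n_syn), y = stats::runif(n_syn), z = stats::runif(n_syn),
        pre_traced = TRUE, post_traced = TRUE,
        stringsAsFactors = FALSE)
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(pre_id = character(), pre_type = character(),
                 post_id = character(), post_type = character(),
                 roi = character(), x = numeric(), y = numeric(), z = numeric(),
                 pre_traced = logical(), post_traced = logical(),
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
    structure(out, true_counts = do.call(rbind, truth),
              class = c("synapse_table", "data.frame"))
  })
}
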