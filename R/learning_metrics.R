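#' Trial-difference learning metric
#'
#' Within one training phase, the change in mean odor response of one fly to
#' one odor: last trial of the phase minus the first (fifth minus first
#' acquisition trial; second minus first reversal trial). A positive value
#' indicates an increase in odor response across the phase.
#'
#' @param responses Response table from [process_experiment()].
#' @param fly Fly id.
#' @param odor `"CSplus"` or `"CSminus"`.
#' @param phase Phase label, e.g. `"acquisition"` or `"reversal"`.
#' @return Scalar difference in dR/R0 units.
#' @export
diff_mean_odor_response <- function(responses, fly, odor, phase) {
  r <- responses[responses$fly_id == fly & responses$odor == odor &
                   responses$phase == phase, , drop = FALSE]
  if (nrow(r) < 2) {
    stop("incomplete phase: fly ", fly, " has ", nrow(r), " ", odor,
         " trial(s) in phase '", phase, "'")
  }
  r <- r[order(r$trial_index), , drop = FALSE]
  r$mean_odor_response[nrow(r)] - r$mean_odor_response[1]
}

#' Odor response trajectory relative to the first acquisition trial
#'
#' Per-trial mean odor response of one fly to one odor, minus that fly's
#' response on its first acquisition trial with the same odor; the first
#' entry is 0 by construction and positive values indicate an increase.
#'
#' @inheritParams diff_mean_odor_response
#' @return Data frame with `trial_index`, `phase`, `rel_response`, ordered
#'   by trial, one row per trial of that odor (acquisition and reversal).
#' @export
relative_to_first_trial <- function(responses, fly, odor) {
  r <- responses[responses$fly_id == fly & responses$odor == odor, , drop = FALSE]
  r <- r[order(r$trial_index), , drop = FALSE]
  first_acq <- r[grepl("acquisition$", r$phase), , drop = FALSE]
  if (nrow(first_acq) == 0) stop("incomplete phase: no acquisition trial for fly ", fly)
  ref <- first_acq$mean_odor_response[which.min(first_acq$trial_index)]
  data.frame(trial_index = r$trial_index, phase = r$phase,
             rel_response = r$mean_odor_response - ref,
             stringsAsFactors = FALSE)
}

#' Per-fly learning summary with group statistics
#'
#' Computes, for every (fly, odor), the acquisition and reversal
#' trial-difference metrics and the per-trial trajectory relative to the
#' first acquisition trial, plus group mean and SEM per odor.
#'
#' @param responses Response table from [process_experiment()].
#' @return A list with `per_fly` (data frame of diffs), `trajectories`
#'   (long data frame) and `group` (mean +/- SEM of each diff per odor).
#' @export
summarize_learning <- function(responses) {
  combos <- unique(responses[, c("fly_id", "odor")])
  per_fly <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    fly <- combos$fly_id[i]; odor <- combos$odor[i]
    has_rev <- any(responses$fly_id == fly & responses$odor == odor &
                     grepl("reversal$", responses$phase))
    acq_phase <- unique(grep("acquisition$",
                             responses$phase[responses$fly_id == fly], value = TRUE))
    rev_phase <- unique(grep("reversal$",
                             responses$phase[responses$fly_id == fly], value = TRUE))
    data.frame(
      fly_id = fly, odor = odor,
      diff_acquisition = diff_mean_odor_response(responses, fly, odor, acq_phase[1]),
      diff_reversal = if (has_rev)
        diff_mean_odor_response(responses, fly, odor, rev_phase[1]) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  traj <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    tr <- relative_to_first_trial(responses, combos$fly_id[i], combos$odor[i])
    cbind(fly_id = combos$fly_id[i], odor = combos$odor[i], tr,
          stringsAsFactors = FALSE)
  }))
  sem <- function(x) stats::sd(x) / sqrt(sum(is.finite(x)))
  group <- do.call(rbind, lapply(split(per_fly, per_fly$odor), function(g) {
    data.frame(odor = g$odor[1],
               mean_diff_acquisition = mean(g$diff_acquisition),
               sem_diff_acquisition = sem(g$diff_acquisition),
               mean_diff_reversal = mean(g$diff_reversal),
               sem_diff_reversal = sem(g$diff_reversal),
               n = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(group) <- NULL
  list(per_fly = per_fly, trajectories = traj, group = group)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the normalising transformations of sample skewness and kurtosis
#' into the omnibus statistic `K2 = Z1(g1)^2 + Z2(g2)^2`, referred to a
#' chi-squared distribution with 2 df. Requires n >= 8 (the kurtosis
#' approximation is undefined below that).
#'
#' @param x Numeric vector, n >= 8.
#' @return A list with `statistic` (K2), `p_value`, `z_skew`, `z_kurt`.
#' @export
dagostino_pearson_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson omnibus test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 == 0) stop("zero variance")
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness: D'Agostino (1970) transformation
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis: Anscombe & Glynn (1983) transformation
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) * sqrt(9 * a / 2)
  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2)
}

#' Normality-gated paired comparison
#'
#' The paired test battery: the paired differences are first screened with
#' the D'Agostino-Pearson omnibus test; if they look Gaussian
#' (`normality_p >= alpha_normality`) a two-tailed paired t-test is used,
#' otherwise a Wilcoxon matched-pairs signed-rank test (zero differences
#' dropped; exact null when n <= 25 and no ties, normal approximation with
#' continuity correction otherwise). For n < 8 the omnibus test is undefined
#' and the Shapiro-Wilk test gates instead.
#'
#' @param x,y Paired per-fly values, equal length >= 3.
#' @param alpha_normality Significance level of the normality gate.
#' @return A list of class `revlearn_test` with `test_name`, `statistic`,
#'   `p_value`, `normality_p`, `n`, `degenerate`.
#' @export
paired_compare <- function(x, y, alpha_normality = 0.05) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs")
  d <- x - y
  if (all(d == 0)) {
    return(structure(list(test_name = "degenerate", statistic = NA_real_,
                          p_value = 1, normality_p = NA_real_,
                          n = length(d), degenerate = TRUE),
                     class = "revlearn_test"))
  }
  norm_p <- if (length(d) >= 8 && stats::sd(d) > 0) {
    dagostino_pearson_test(d)$p_value
  } else if (stats::sd(d) > 0) {
    stats::shapiro.test(d)$p.value
  } else NA_real_
  if (!is.na(norm_p) && norm_p >= alpha_normality) {
    tt <- stats::t.test(x, y, paired = TRUE)
    res <- list(test_name = "paired t-test", statistic = unname(tt$statistic),
                p_value = tt$p.value, normality_p = norm_p,
                n = length(d), degenerate = FALSE)
  } else {
    dz <- d[d != 0]  # drop zero differences
    exact <- length(dz) <= 25 && !any(duplicated(abs(dz)))
    wt <- suppressWarnings(
      stats::wilcox.test(dz, exact = exact, correct = TRUE))
    res <- list(test_name = "wilcoxon signed-rank", statistic = unname(wt$statistic),
                p_value = wt$p.value, normality_p = norm_p,
                n = length(d), degenerate = FALSE)
  }
  structure(res, class = "revlearn_test")
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity correction factor estimated from the sample covariance of the
#' within-subject measurements: with `C` an orthonormal contrast basis
#' orthogonal to the unit vector and `S` the k x k sample covariance,
#' `epsilon = tr(CSC')^2 / ((k-1) * tr((CSC')^2))`. Equals 1 exactly under
#' compound symmetry and is bounded below by `1/(k-1)`.
#'
#' @param Y n x k matrix (subjects x within-subject levels).
#' @return Scalar epsilon in `[1/(k-1), 1]`.
#' @export
greenhouse_geisser_epsilon <- function(Y) {
  Y <- as.matrix(Y)
  k <- ncol(Y)
  S <- stats::cov(Y)
  C <- stats::contr.helmert(k)
  C <- qr.Q(qr(C))  # orthonormal contrasts
  V <- t(C) %*% S %*% C
  eps <- sum(diag(V))^2 / ((k - 1) * sum(V * V))
  min(max(eps, 1 / (k - 1)), 1)
}

#' Dunnett-style adjusted p-values
#'
#' Two-sided familywise-adjusted p-values for comparing each of m treatment
#' statistics against a shared control, using the classic multivariate-t
#' distribution with pairwise correlation 1/2 among the m contrasts.
#' Quadrature is via `mvtnorm::pmvt` with tight absolute tolerance; the RNG
#' state used internally by the integration is fixed so results are
#' deterministic.
#'
#' @param tstats Vector of m contrast t statistics.
#' @param df Error degrees of freedom.
#' @return Vector of adjusted p-values.
#' @export
dunnett_adjusted_p <- function(tstats, df) {
  m <- length(tstats)
  corr <- matrix(0.5, m, m); diag(corr) <- 1
  vapply(tstats, function(tj) {
    a <- abs(tj)
    pr <- withr::with_seed(20260920, mvtnorm::pmvt(
      lower = rep(-a, m), upper = rep(a, m), df = as.integer(round(df)),
      corr = corr, algorithm = mvtnorm::GenzBretz(abseps = 1e-6, maxpts = 1e6)))
    max(0, min(1, 1 - as.numeric(pr)))
  }, numeric(1))
}

#' Repeated-measures ANOVA with Dunnett-style post-hoc vs the first trial
#'
#' Univariate repeated-measures ANOVA over trials. With a single odor the
#' design is one-way within-subject (trial); with two odors it is a two-way
#' within-subject design (trial x odor) and the reported omnibus test is the
#' trial x odor interaction, i.e. whether the trial course differs between
#' CS+ and CS-. The Greenhouse-Geisser epsilon multiplies both degrees of
#' freedom of the tested effect when `apply_gg = TRUE`. Post-hoc Dunnett
#' comparisons test each later trial against the first trial (per odor in
#' the two-way case, on the CS+ - CS- difference scores).
#'
#' @param trajectories Long data frame with columns `fly_id`, `trial_index`,
#'   `rel_response` and optionally `odor` (as from
#'   [summarize_learning()]`$trajectories`).
#' @param apply_gg Apply the Greenhouse-Geisser df correction.
#' @param posthoc Compute the Dunnett comparisons (skippable because the
#'   multivariate-t quadrature dominates runtime in large simulations where
#'   only the omnibus test is of interest).
#' @return A list of class `revlearn_test` with `test_name`, `statistic`
#'   (F), `df`, `p_value`, `gg_epsilon`, `posthoc` (data frame of trial
#'   vs first-trial comparisons with adjusted p-values).
#' @export
rm_anova_dunnett <- function(trajectories, apply_gg = TRUE, posthoc = TRUE) {
  d <- as.data.frame(trajectories)
  stopifnot(all(c("fly_id", "trial_index", "rel_response") %in% names(d)))
  odors <- if ("odor" %in% names(d)) unique(d$odor) else "all"
  two_way <- length(odors) == 2
  if (two_way) {
    # difference scores CS+ - CS- turn the interaction into a one-way design
    wide_p <- to_wide(d[d$odor == odors[1], ])
    wide_m <- to_wide(d[d$odor == odors[2], ])
    if (!identical(dim(wide_p), dim(wide_m)) ||
        !identical(rownames(wide_p), rownames(wide_m))) {
      stop("unbalanced design: both odors must cover the same flies and trials")
    }
    Y <- wide_p - wide_m
    label <- "rm-anova trial x odor interaction"
  } else {
    Y <- to_wide(d)
    label <- "rm-anova trial effect"
  }
  n <- nrow(Y); k <- ncol(Y)
  if (n < 2 || k < 2) stop("need >= 2 flies and >= 2 trials")
  grand <- mean(Y)
  ss_subj <- k * sum((rowMeans(Y) - grand)^2)
  ss_trial <- n * sum((colMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_trial
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  ms_trial <- ss_trial / df1; ms_err <- ss_err / df2
  Fstat <- ms_trial / ms_err
  eps <- greenhouse_geisser_epsilon(Y)
  use_eps <- if (apply_gg) eps else 1
  p <- stats::pf(Fstat, use_eps * df1, use_eps * df2, lower.tail = FALSE)
  # Dunnett: each later trial vs the first, pooled RM error, corr 1/2
  ph <- NULL
  if (posthoc) {
    dmeans <- colMeans(Y[, -1, drop = FALSE]) - mean(Y[, 1])
    se <- sqrt(2 * ms_err / n)
    tstats <- dmeans / se
    adj <- dunnett_adjusted_p(tstats, df2)
    ph <- data.frame(
      comparison = paste0("trial", colnames(Y)[-1], " - trial", colnames(Y)[1]),
      estimate = dmeans, t = tstats, adjusted_p = adj,
      stringsAsFactors = FALSE)
    rownames(ph) <- NULL
  }
  structure(list(test_name = label, statistic = Fstat,
                 df = c(use_eps * df1, use_eps * df2), p_value = p,
                 gg_epsilon = eps, applied_gg = apply_gg, posthoc = ph),
            class = "revlearn_test")
}

# flies x trials wide matrix; errors if coverage is ragged
to_wide <- function(d) {
  tab <- table(d$fly_id, d$trial_index)
  if (any(tab != 1)) stop("unbalanced design: every fly needs exactly one value per trial")
  flies <- sort(unique(d$fly_id)); trials <- sort(unique(d$trial_index))
  Y <- matrix(NA_real_, length(flies), length(trials),
              dimnames = list(flies, trials))
  Y[cbind(match(d$fly_id, flies), match(d$trial_index, trials))] <- d$rel_response
  Y
}

#' @export
print.revlearn_test <- function(x, ...) {
  cat(x$test_name, "\n")
  if (!is.null(x$normality_p)) cat("  normality p:", format(x$normality_p), "\n")
  cat("  statistic:", format(x$statistic), " p:", format(x$p_value), "\n")
  if (!is.null(x$posthoc)) {
    cat("  post-hoc vs first trial:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}
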