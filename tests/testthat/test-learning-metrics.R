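fake_responses <- function(values, odor = "CSplus", phase = "acquisition",
                           fly = "f1") {
  data.frame(fly_id = fly, neuron_class = "x",
             trial_index = seq_along(values) * 2 - 1, phase = phase,
             odor = odor, mean_odor_response = values,
             mean_shock_response = NA_real_, fit_ok = TRUE,
             stringsAsFactors = FALSE)
}

test_that("trial-difference metric is last minus first within the phase", {
  r <- fake_responses(c(0.8, 0.6, 0.5, 0.4, 0.3))
  expect_equal(diff_mean_odor_response(r, "f1", "CSplus", "acquisition"), -0.5)
  r2 <- fake_responses(c(0.4, 0.4))
  expect_equal(diff_mean_odor_response(r2, "f1", "CSplus", "acquisition"), 0)
  expect_error(diff_mean_odor_response(fake_responses(0.5), "f1", "CSplus",
                                       "acquisition"), "incomplete phase")
})

test_that("trial differences are antisymmetric and shift invariant", {
  withr::with_seed(5, {
    for (i in 1:10) {
      v <- rnorm(5)
      r <- fake_responses(v)
      fwd <- diff_mean_odor_response(r, "f1", "CSplus", "acquisition")
      rbk <- fake_responses(rev(v))
      expect_equal(diff_mean_odor_response(rbk, "f1", "CSplus", "acquisition"), -fwd)
      shifted <- fake_responses(v + 3.7)
      expect_equal(diff_mean_odor_response(shifted, "f1", "CSplus", "acquisition"), fwd)
      tr <- relative_to_first_trial(r, "f1", "CSplus")$rel_response
      tr_sh <- relative_to_first_trial(shifted, "f1", "CSplus")$rel_response
      expect_equal(tr, tr_sh)
    }
  })
})

test_that("trajectory is response minus first acquisition trial, first entry zero", {
  r <- fake_responses(c(0.5, 0.4, 0.3))
  traj <- relative_to_first_trial(r, "f1", "CSplus")
  expect_equal(traj$rel_response, c(0, -0.1, -0.2))
  expect_equal(nrow(traj), 3L)
  const <- relative_to_first_trial(fake_responses(rep(0.2, 4)), "f1", "CSplus")
  expect_equal(const$rel_response, rep(0, 4))
  # reversal trials are referenced to the first *acquisition* trial
  r2 <- rbind(fake_responses(c(0.5, 0.3)),
              fake_responses(c(0.6, 0.7), phase = "reversal"))
  r2$trial_index <- c(1, 3, 11, 13)
  traj2 <- relative_to_first_trial(r2, "f1", "CSplus")
  expect_equal(traj2$rel_response, c(0, -0.2, 0.1, 0.2))
})

test_that("learning summary mirrors the simulated plasticity profile", {
  s <- generate_trial_schedule(5, 2)
  cfg <- sim_config(motion_sd = 0, noise_sd = 0, fly_amp_cv = 0)
  traces <- simulate_experiment(cfg, s, n_flies = 3,
                                plasticity = plasticity_preset("pam_b2a"), seed = 2)
  resp <- process_experiment(traces, s)
  summ <- summarize_learning(resp)
  plus <- summ$per_fly[summ$per_fly$odor == "CSplus", ]
  expect_true(all(plus$diff_acquisition < 0))
  expect_true(all(plus$diff_reversal > 0))
  first_entries <- summ$trajectories[!duplicated(
    paste(summ$trajectories$fly_id, summ$trajectories$odor)), ]
  expect_true(all(first_entries$rel_response == 0))
  expect_equal(sort(summ$group$odor), c("CSminus", "CSplus"))
})

test_that("D'Agostino-Pearson omnibus matches an external reference implementation", {
  # reference values computed once with scipy.stats.normaltest 1.17
  x <- c(0.12, -0.54, 0.71, 1.33, -0.02, 0.46, -1.21, 0.88, 0.35, -0.66,
         0.18, 1.02, -0.44, 0.59, -0.91, 0.27, 0.73, -0.15, 0.41, -0.33)
  res <- dagostino_pearson_test(x)
  expect_equal(res$statistic, 0.4864999712449213, tolerance = 1e-10)
  expect_equal(res$p_value, 0.7840754816726321, tolerance = 1e-10)
  y <- c(3.1, 2.2, 5.9, 4.4, 1.0, 0.5, 0.8, 7.2, 6.6, 2.9, 3.3, 4.1)
  res2 <- dagostino_pearson_test(y)
  expect_equal(res2$statistic, 0.8647653477479366, tolerance = 1e-10)
  expect_equal(res2$p_value, 0.6489609887467733, tolerance = 1e-10)
  expect_error(dagostino_pearson_test(rnorm(7)), "n >= 8")
})

test_that("paired comparison gates on normality and handles degeneracy", {
  x <- c(1.2, 0.8, 1.5, 1.1, 0.9, 1.3, 1.0, 1.4, 0.7)
  expect_equal(paired_compare(x, x)$p_value, 1)
  expect_true(paired_compare(x, x)$degenerate)

  y <- x + c(0.28, 0.33, 0.25, 0.36, 0.31, 0.22, 0.35, 0.27, 0.30)
  res <- paired_compare(x, y)
  expect_gte(res$normality_p, 0.05)
  expect_equal(res$test_name, "paired t-test")
  expect_equal(res$statistic, oracle_paired_t(x, y), tolerance = 1e-12)
  expect_equal(res$p_value, stats::t.test(x, y, paired = TRUE)$p.value)

  # grossly non-Gaussian differences are routed to the signed-rank test
  withr::with_seed(9, {
    n <- 40
    d <- c(rexp(n - 4, 1), 60, 80, -90, 70)
    res <- paired_compare(d, rep(0, n))
    expect_equal(res$test_name, "wilcoxon signed-rank")
    expect_lt(res$normality_p, 0.05)
    expect_true(res$p_value >= 0 && res$p_value <= 1)
  })
  expect_error(paired_compare(1:2, 2:3), "at least 3")
})

test_that("Greenhouse-Geisser epsilon is 1 under exact compound symmetry", {
  S <- matrix(0.4, 5, 5); diag(S) <- 1
  Y <- matrix_with_cov(12, S, seed = 3)
  expect_equal(greenhouse_geisser_epsilon(Y), 1, tolerance = 1e-10)
  # strong sphericity violation pushes epsilon well below 1
  S2 <- diag(c(4, 1, 0.25, 0.1, 0.05))
  Y2 <- matrix_with_cov(12, S2, seed = 4)
  expect_lt(greenhouse_geisser_epsilon(Y2), 0.8)
  expect_gte(greenhouse_geisser_epsilon(Y2), 1 / 4)
})

test_that("repeated-measures F matches brute-force sums of squares and aov", {
  toy <- matrix(c(1, 2, 3,
                  2, 3, 5,
                  0, 1, 2,
                  1, 3, 4), nrow = 4, byrow = TRUE)
  traj <- data.frame(fly_id = rep(paste0("f", 1:4), each = 3),
                     trial_index = rep(1:3, 4),
                     rel_response = as.vector(t(toy)))
  res <- rm_anova_dunnett(traj, apply_gg = FALSE)
  expect_equal(res$statistic, oracle_rm_F(toy), tolerance = 1e-12)
  # aov with a within-subject error stratum as a second, independent check
  fit <- stats::aov(rel_response ~ factor(trial_index) +
                      Error(factor(fly_id) / factor(trial_index)), data = traj)
  tab <- summary(fit)[["Error: factor(fly_id):factor(trial_index)"]][[1]]
  expect_equal(res$statistic, tab[["F value"]][1], tolerance = 1e-10)
  expect_equal(res$p_value, tab[["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("Dunnett adjusted p-values agree with a Monte-Carlo max-|t| oracle", {
  adj <- dunnett_adjusted_p(c(2.2, 0.8, 3.1, 1.5), df = 32)
  for (i in seq_along(adj)) {
    mc <- oracle_dunnett_p(c(2.2, 0.8, 3.1, 1.5)[i], m = 4, df = 32)
    expect_lt(abs(adj[i] - mc), 0.01)
  }
  # familywise adjustment can only increase the unadjusted two-sided p
  unadj <- 2 * stats::pt(abs(c(2.2, 0.8, 3.1, 1.5)), 32, lower.tail = FALSE)
  expect_true(all(adj >= unadj - 1e-9))
  # deterministic across calls
  expect_identical(adj, dunnett_adjusted_p(c(2.2, 0.8, 3.1, 1.5), df = 32))
})

test_that("rm_anova_dunnett posthoc compares every later trial to the first", {
  withr::with_seed(14, {
    traj <- data.frame(fly_id = rep(paste0("f", 1:8), each = 5),
                       trial_index = rep(1:5, 8),
                       rel_response = rnorm(40) + rep(c(0, 0, 0.3, 0.8, 1.2), 8))
    res <- rm_anova_dunnett(traj, apply_gg = TRUE)
    expect_equal(nrow(res$posthoc), 4L)
    expect_true(all(grepl("- trial1$", res$posthoc$comparison)))
    expect_lt(res$posthoc$adjusted_p[4], 0.05)  # large late effect detected
    expect_true(res$gg_epsilon <= 1 && res$gg_epsilon >= 0.25)
  })
  bad <- data.frame(fly_id = c("a", "a", "b"), trial_index = c(1, 2, 1),
                    rel_response = 1:3)
  expect_error(rm_anova_dunnett(bad), "unbalanced")
})

test_that("GG correction never rejects more than the uncorrected F under sphericity", {
  withr::with_seed(22, {
    cmp <- replicate(300, {
      traj <- data.frame(fly_id = rep(1:9, each = 5), trial_index = rep(1:5, 9),
                         rel_response = rnorm(45))
      c(gg = rm_anova_dunnett(traj, apply_gg = TRUE, posthoc = FALSE)$p_value < 0.05,
        raw = rm_anova_dunnett(traj, apply_gg = FALSE, posthoc = FALSE)$p_value < 0.05)
    })
    expect_lte(mean(cmp["gg", ]), mean(cmp["raw", ]))
  })
})

test_that("two-odor input tests the trial-by-odor interaction on difference scores", {
  withr::with_seed(15, {
    n <- 9; k <- 5
    base <- data.frame(fly_id = rep(paste0("f", 1:n), each = k),
                       trial_index = rep(1:k, n))
    csplus <- cbind(base, odor = "CSplus",
                    rel_response = rnorm(n * k, sd = 0.3) +
                      rep(seq(0, -1, length.out = k), n))
    csminus <- cbind(base, odor = "CSminus", rel_response = rnorm(n * k, sd = 0.3))
    res <- rm_anova_dunnett(rbind(csplus, csminus), apply_gg = TRUE)
    expect_match(res$test_name, "interaction")
    expect_lt(res$p_value, 0.01)  # diverging trajectories are detected
  })
})
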