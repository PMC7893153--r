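# Independent oracles, deliberately coded on different paths than the package.

# Closed-form discrete window mean of the unit-peak difference-of-exponentials
# kernel sampled at m frames spaced dt, starting at the event onset.
# Uses geometric-series sums, not pointwise kernel evaluation.
oracle_kernel_window_mean <- function(rise, decay, dt, m) {
  tpk <- log(decay / rise) * rise * decay / (decay - rise)
  peak <- exp(-tpk / decay) - exp(-tpk / rise)
  geom <- function(tau) {
    r <- exp(-dt / tau)
    (1 - r^m) / (1 - r)
  }
  (geom(decay) - geom(rise)) / (m * peak)
}

# Grid + profiled-linear + L-BFGS-B refinement fit of
# a1*exp(-t/tau1) + a2*exp(-t/tau2) + c. Independent of minpack.lm.
oracle_fit_double_exp <- function(y, t, tau_range = c(2, 600), n_grid = 24) {
  taus <- exp(seq(log(tau_range[1]), log(tau_range[2]), length.out = n_grid))
  rss_lin <- function(lt) {
    tau1 <- exp(lt[1]); tau2 <- exp(lt[2])
    X <- cbind(exp(-t / tau1), exp(-t / tau2), 1)
    qr_f <- qr(X)
    res <- qr.resid(qr_f, y)
    sum(res^2)
  }
  cand <- list()
  for (i in seq_len(n_grid - 1)) {
    for (j in seq(i + 1, n_grid)) {
      lt <- log(c(taus[i], taus[j]))
      cand[[length(cand) + 1L]] <- list(lt = lt, rss = rss_lin(lt))
    }
  }
  cand <- cand[order(vapply(cand, `[[`, numeric(1), "rss"))]
  # refine from the few best grid starts; keep the overall best
  opts <- lapply(cand[seq_len(min(3, length(cand)))], function(cc) {
    stats::optim(cc$lt, rss_lin, method = "L-BFGS-B",
                 lower = log(c(0.1, 0.1)), upper = log(c(5000, 5000)),
                 control = list(factr = 10, maxit = 500))
  })
  opt <- opts[[which.min(vapply(opts, `[[`, numeric(1), "value"))]]
  tau <- sort(exp(opt$par))
  X <- cbind(exp(-t / tau[1]), exp(-t / tau[2]), 1)
  co <- qr.coef(qr(X), y)
  c(a1 = unname(co[1]), tau1 = tau[1], a2 = unname(co[2]), tau2 = tau[2],
    c = unname(co[3]))
}

# Brute-force windowed mean: explicit frame loop.
oracle_window_mean <- function(x, t, start, end) {
  s <- 0; n <- 0
  for (i in seq_along(t)) {
    if (t[i] >= start && t[i] < end) { s <- s + x[i]; n <- n + 1 }
  }
  s / n
}

# Textbook paired t statistic.
oracle_paired_t <- function(x, y) {
  d <- x - y; n <- length(d)
  mean(d) / (sqrt(sum((d - mean(d))^2) / (n - 1)) / sqrt(n))
}

# Brute-force repeated-measures one-way ANOVA F via explicit sums of squares.
oracle_rm_F <- function(Y) {
  n <- nrow(Y); k <- ncol(Y); g <- mean(Y)
  ss_s <- 0; for (i in 1:n) ss_s <- ss_s + k * (mean(Y[i, ]) - g)^2
  ss_t <- 0; for (j in 1:k) ss_t <- ss_t + n * (mean(Y[, j]) - g)^2
  ss_tot <- 0; for (i in 1:n) for (j in 1:k) ss_tot <- ss_tot + (Y[i, j] - g)^2
  ss_e <- ss_tot - ss_s - ss_t
  (ss_t / (k - 1)) / (ss_e / ((n - 1) * (k - 1)))
}

# Monte-Carlo Dunnett familywise p for max-|t| with correlation 1/2.
oracle_dunnett_p <- function(tstat, m, df, nsim = 2e5, seed = 42) {
  withr::with_seed(seed, {
    corr <- matrix(0.5, m, m); diag(corr) <- 1
    Z <- mvtnorm::rmvt(nsim, sigma = corr, df = df)
    mean(apply(abs(Z), 1, max) >= abs(tstat))
  })
}

# Nested-loop pairwise synapse counts.
oracle_pair_counts <- function(tab, pre_type, post_type,
                               pre_roster = NULL, post_roster = NULL) {
  rows <- tab[tab$pre_type == pre_type & tab$post_type == post_type, , drop = FALSE]
  pres <- if (is.null(pre_roster)) unique(rows$pre_id) else pre_roster
  posts <- if (is.null(post_roster)) unique(rows$post_id) else post_roster
  out <- list()
  for (p in pres) for (q in posts) {
    cnt <- 0
    for (r in seq_len(nrow(rows))) {
      if (rows$pre_id[r] == p && rows$post_id[r] == q) cnt <- cnt + 1
    }
    out[[length(out) + 1L]] <- data.frame(pre_id = p, post_id = q, count = cnt,
                                          stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(pre_roster)) res <- res[res$count > 0, , drop = FALSE]
  res <- res[order(res$pre_id, res$post_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Construct an n x k data matrix whose sample covariance equals S exactly.
matrix_with_cov <- function(n, S, seed = 1) {
  k <- ncol(S)
  withr::with_seed(seed, {
    Y0 <- matrix(stats::rnorm(n * k), n, k)
    Y0 <- scale(Y0, center = TRUE, scale = FALSE)
    Y0 %*% solve(chol(stats::cov(Y0))) %*% chol(S)
  })
}
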