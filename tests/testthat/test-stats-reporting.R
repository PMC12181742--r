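test_that("the signed-rank test agrees with independent references", {
  set.seed(7)
  x <- rnorm(12); y <- rnorm(12)
  ours <- wilcoxon_signed_rank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_lt(abs(ours$W - unname(ref$statistic)), 1e-6)
  expect_lt(abs(ours$p - ref$p.value), 1e-6)
  # brute-force sign enumeration oracle
  br <- enumerate_signed_rank(x - y)
  expect_equal(ours$W, br$W)
  expect_lt(abs(ours$p - br$p), 1e-6)
  expect_true(ours$r >= 0 && ours$r <= 1)
  # identical columns: degenerate, reported as not significant
  z <- wilcoxon_signed_rank(x, x)
  expect_equal(z$p, 1)
  expect_equal(z$r, 0)
})

test_that("pairwise Wilcoxon applies the Holm correction across the family", {
  set.seed(8)
  tb <- expand.grid(participant = 1:15, condition = c("a", "b", "c"))
  tb$intensity <- rnorm(45) + (tb$condition == "c") * 1.5
  res <- pairwise_wilcoxon_holm(tb)
  expect_equal(nrow(res), 3)
  # Holm property: adjusted values non-decreasing in raw-p order
  o <- order(res$p)
  expect_true(all(diff(res$padj[o]) >= -1e-12))
  expect_true(all(res$padj >= res$p))
  expect_true(all(res$padj <= 1))
  # too few non-zero differences: skipped with a warning
  tb2 <- expand.grid(participant = 1:6, condition = c("a", "b"))
  tb2$intensity <- rep(1, 12); tb2$intensity[1] <- 2
  expect_warning(res2 <- pairwise_wilcoxon_holm(tb2), "fewer than 5")
  expect_true(is.na(res2$W[1]))
})

test_that("Friedman omnibus and Kendall's W match a brute-force rank computation", {
  m <- matrix(c(3, 1, 2, 4,
                2, 1, 3, 4,
                3, 2, 1, 4,
                1, 3, 2, 4,
                2, 1, 4, 3,
                3, 1, 2, 4), 6, 4, byrow = TRUE)
  fr <- friedman_kendall(m)
  expect_equal(fr$chi_squared, brute_force_friedman(m), tolerance = 1e-6)
  expect_equal(fr$df, 3)
  # identical columns: no concordance signal
  same <- matrix(rep(c(1, 5, 2, 4), 4), 4, 4)
  fr0 <- friedman_kendall(same)
  expect_equal(fr0$chi_squared, 0)
  expect_equal(fr0$kendall_w, 0)
  # perfectly consistent rankings: maximal concordance
  perf <- matrix(rep(1:4, each = 5), 5, 4)
  expect_equal(friedman_kendall(perf)$kendall_w, 1)
  expect_error(friedman_kendall(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
})

test_that("the empirical power simulation is calibrated and monotone", {
  p0 <- wilcoxon_power_sim(20, 0, n_reps = 500, seed = 3)
  se <- sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(p0 - 0.05), 2 * se)
  expect_gt(wilcoxon_power_sim(20, 3, n_reps = 300, seed = 4), 0.99)
  grid <- vapply(c(0, 0.25, 0.5, 1), function(s)
    wilcoxon_power_sim(20, s, n_reps = 400, seed = 5), numeric(1))
  expect_true(all(diff(grid) >= 0))
})

test_that("the effect-size shift calibration reaches its target", {
  sh <- shift_for_effect(0.5, n = 20, n_reps = 300, seed = 9)
  rb <- mean(vapply(1:400, function(b) {
    set.seed(10000 + b)
    dd <- (rexp(20) - 1 + sh) - (rexp(20) - 1)
    rk <- rank(abs(dd))
    2 * sum(rk[dd > 0]) / (20 * 21 / 2) - 1
  }, numeric(1)))
  expect_lt(abs(rb - 0.5), 0.1)
})

test_that("the mixed model recovers planted effects and is calibrated under the null", {
  suppressMessages(suppressWarnings({
    ok <- vapply(1:100, function(s) {
      set.seed(s)
      N <- 30; J <- 5
      tb <- expand.grid(participant = factor(1:N), condition = 1:J)
      tb$EE <- sample(1:5, N * J, TRUE)
      tb$MVR <- rlnorm(N * J, 0, 0.4)
      u <- rnorm(N, 0, 0.1)
      tb$intensity <- exp(1 - 0.05 * tb$EE - 0.22 * log(tb$MVR) +
                            u[as.integer(tb$participant)] + rnorm(N * J, 0, 0.15))
      fit <- fit_mixed_model(tb, ~ EE + log(MVR))
      cf <- fit$coefficients
      abs(cf["EE", "Estimate"] + 0.05) < 1.96 * cf["EE", "Std. Error"] &&
        abs(cf["log(MVR)", "Estimate"] + 0.22) < 1.96 * cf["log(MVR)", "Std. Error"]
    }, logical(1))
    expect_gte(mean(ok), 0.90)
  }))
})

test_that("mixed-model outputs are well-formed and R2 is bounded", {
  suppressMessages(suppressWarnings({
    set.seed(77)
    N <- 20; J <- 4
    tb <- expand.grid(participant = factor(1:N), condition = 1:J)
    tb$EE <- sample(1:5, N * J, TRUE)
    tb$MVR <- rlnorm(N * J, 0, 0.4)
    tb$intensity <- exp(rnorm(N * J) + rnorm(N, 0, 0.3)[as.integer(tb$participant)])
    fit <- fit_mixed_model(tb, ~ EE + log(MVR))
    expect_true(fit$r2_conditional >= 0 && fit$r2_conditional <= 1)
    expect_true(all(c("Estimate", "Pr(>|t|)") %in% colnames(fit$coefficients)))
    expect_true(is.finite(fit$AIC) && is.finite(fit$logLik))
    expect_error(fit_mixed_model(transform(tb, intensity = intensity - 10),
                                 ~ EE), "positive")
  }))
})

test_that("turbulence differences injected via nonstationarity are detected end to end", {
  det <- vapply(1:5, function(s) {
    cfg <- small_config(N = 30, J = 2, K = 4, fs = 200, duration = 4, snr = 4,
                        noise_seed = 100 + s, mixing_seed = 50 + s)
    d <- generate_dataset(cfg)
    sub <- d; sub$data <- d$data[, 2, , , drop = FALSE]
    sub <- inject_nonstationarity(sub, 1.5, seed = 300 + s)
    d$data[, 2, , ] <- sub$data[, 1, , ]
    it <- turbulence_intensity(turbulence_field(d, 500, hop = 100, p = 5))
    pairwise_wilcoxon_holm(it)$padj[1] < 0.05
  }, logical(1))
  expect_gte(mean(det), 0.8)
})
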