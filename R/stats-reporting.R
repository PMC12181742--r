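#' Paired Wilcoxon signed-rank test with Pratt zero handling
#'
#' Computes the signed-rank statistic W (sum of positive ranks), a two-sided
#' p value, and the effect size `r = |Z| / sqrt(n)`. Zero differences are
#' handled by the Pratt method: they participate in the ranking and are then
#' dropped from the statistic, with the null mean/variance adjusted
#' accordingly. When there are no zeros, no ties, and at most 50 pairs the p
#' value is exact (signed-rank distribution); otherwise the normal
#' approximation with tie correction is used. Z for the effect size always
#' comes from the (tie/zero-adjusted) normal approximation.
#'
#' @param x,y Paired numeric vectors (`y` may be `NULL` if `x` already holds
#'   differences).
#' @return List with `W`, `p`, `z`, `r`, `n` (pairs), `n_zero`, `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  n_all <- length(d)
  zero <- d == 0
  n0 <- sum(zero)
  rk <- rank(abs(d))            # zeros included in the ranking (Pratt)
  W <- sum(rk[d > 0])
  n <- n_all
  ties <- table(rk[!zero])
  has_ties <- any(ties > 1)
  mu <- n * (n + 1) / 4 - n0 * (n0 + 1) / 4
  sig2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    sum(ties^3 - ties) / 48
  if (sig2 <= 0) {              # all differences zero: degenerate
    return(list(W = W, p = 1, z = 0, r = 0, n = n_all, n_zero = n0,
                exact = FALSE))
  }
  z <- (W - mu) / sqrt(sig2)
  exact <- n0 == 0 && !has_ties && n_all <= 50
  p <- if (exact) {
    min(1, 2 * min(psignrank(W, n_all), 1 - psignrank(W - 1, n_all)))
  } else {
    2 * pnorm(-abs(z))
  }
  list(W = W, p = p, z = z, r = min(1, abs(z) / sqrt(n_all)), n = n_all,
       n_zero = n0, exact = exact)
}

#' Pairwise Wilcoxon tests between conditions with Holm correction
#'
#' Runs two-sided paired Wilcoxon signed-rank tests for every requested pair
#' of conditions on an intensity table, matching observations by
#' participant, and applies the Bonferroni-Holm correction across the pair
#' family. Pairs with fewer than 5 non-zero paired differences are skipped
#' with a warning and reported as `NA`.
#'
#' @param table Data frame with columns `participant`, `condition`, and the
#'   response column `value_col` (unique participant x condition keys).
#' @param pairs List of length-2 character vectors of condition names, or
#'   `NULL` for all pairs.
#' @param value_col Response column name (default `"intensity"`).
#' @return Data frame with one row per pair: `condition_a`, `condition_b`,
#'   `n`, `W`, `p`, `padj`, `r`.
#' @export
pairwise_wilcoxon_holm <- function(table, pairs = NULL,
                                   value_col = "intensity") {
  stopifnot(all(c("participant", "condition", value_col) %in% names(table)))
  conds <- unique(table$condition)
  if (is.null(pairs)) {
    cmb <- utils::combn(conds, 2, simplify = FALSE)
  } else cmb <- pairs
  rows <- lapply(cmb, function(pr) {
    a <- table[table$condition == pr[1], c("participant", value_col)]
    b <- table[table$condition == pr[2], c("participant", value_col)]
    m <- merge(a, b, by = "participant")
    d <- m[[2]] - m[[3]]
    if (sum(d != 0) < 5) {
      warning(sprintf("pair %s-%s: fewer than 5 non-zero differences; skipped",
                      pr[1], pr[2]))
      return(data.frame(condition_a = pr[1], condition_b = pr[2],
                        n = length(d), W = NA_real_, p = NA_real_,
                        r = NA_real_))
    }
    ts <- wilcoxon_signed_rank(d)
    data.frame(condition_a = pr[1], condition_b = pr[2], n = ts$n,
               W = ts$W, p = ts$p, r = ts$r)
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p, method = "holm")
  out[, c("condition_a", "condition_b", "n", "W", "p", "padj", "r")]
}

#' Friedman omnibus test with Kendall's W
#'
#' Friedman chi-squared test on within-participant ranks across conditions,
#' plus the concordance coefficient `W = chi2 / (N (J - 1))`.
#'
#' @param mat Complete numeric matrix, participants x conditions (at least
#'   2 of each).
#' @return List with `chi_squared`, `p`, `kendall_w`, `df`.
#' @export
friedman_kendall <- function(mat) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat))) stop("matrix must be complete")
  if (nrow(mat) < 2 || ncol(mat) < 2) stop("need >= 2 participants and conditions")
  ft <- friedman.test(mat)
  chi2 <- unname(ft$statistic)
  if (!is.finite(chi2)) {  # all within-row ranks tied: no concordance signal
    return(list(chi_squared = 0, p = 1, kendall_w = 0,
                df = unname(ft$parameter)))
  }
  list(chi_squared = chi2, p = ft$p.value,
       kendall_w = chi2 / (nrow(mat) * (ncol(mat) - 1)),
       df = unname(ft$parameter))
}

#' Empirical power of the paired Wilcoxon test under exp(1) - 1 noise
#'
#' Simulates paired samples whose per-arm values are exp(1) - 1 draws (a
#' heavy-tailed, zero-mean noise model), adds a location shift to one arm,
#' and reports the fraction of replicates in which the two-sided signed-rank
#' test rejects at `alpha`. Because the paired differences of two i.i.d.
#' exp(1) - 1 arms are symmetric about the shift, the rejection rate at
#' `shift = 0` equals `alpha`.
#'
#' @param n Pairs per replicate (>= 5).
#' @param shift Location shift added to one arm.
#' @param n_reps Replicates (>= 100).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @return Scalar empirical power.
#' @export
wilcoxon_power_sim <- function(n, shift, n_reps = 1000, alpha = 0.05,
                               seed = 1L) {
  stopifnot(n >= 5, n_reps >= 100)
  with_seed(seed, {
    rej <- vapply(seq_len(n_reps), function(b) {
      x <- rexp(n) - 1 + shift
      y <- rexp(n) - 1
      wilcoxon_signed_rank(x, y)$p < alpha
    }, logical(1))
    mean(rej)
  })
}

#' Shift calibration for a target matched rank-biserial effect size
#'
#' Maps a target rank-biserial correlation to the location shift of the
#' exp(1) - 1 power simulation by root-finding on the simulated mean effect.
#'
#' @param r_target Target rank-biserial correlation in (0, 1).
#' @param n Pairs per replicate.
#' @param n_reps Replicates per evaluation.
#' @param seed Integer seed.
#' @param interval Search interval for the shift.
#' @return Scalar shift.
#' @export
shift_for_effect <- function(r_target, n, n_reps = 400, seed = 1L,
                             interval = c(0, 8)) {
  stopifnot(r_target > 0, r_target < 1)
  mean_rb <- function(shift) {
    with_seed(seed, {
      mean(vapply(seq_len(n_reps), function(b) {
        d <- (rexp(n) - 1 + shift) - (rexp(n) - 1)
        rk <- rank(abs(d))
        V <- sum(rk[d > 0])
        2 * V / (n * (n + 1) / 2) - 1
      }, numeric(1)))
    })
  }
  stats::uniroot(function(s) mean_rb(s) - r_target, interval,
                 tol = 1e-3)$root
}

#' Mixed-effects model on a turbulence intensity table
#'
#' Thin plumbing over the REML fitter in \pkg{lme4}/\pkg{lmerTest}: fits
#' `log(response) ~ fixed + (1 | participant)` (no random slopes) and
#' reports fixed-effect estimates with Satterthwaite p values, AIC,
#' log-likelihood, and the conditional R-squared from the Nakagawa variance
#' decomposition. A singular fit triggers a warning with the
#' variance-component report.
#'
#' @param table Data frame with columns `participant`, the response, and the
#'   predictors named in `fixed` (e.g. an intensity table joined with
#'   behavioral covariates).
#' @param fixed One-sided formula of fixed-effect terms, e.g.
#'   `~ log(EE) + log(MVR)`.
#' @param response Response column name (default `"intensity"`).
#' @param log_response Model the response on the log scale (default `TRUE`;
#'   requires positive values).
#' @return Object of class `mem_fit`: `model` (the `lmerMod`),
#'   `coefficients` (estimate/SE/df/t/p), `AIC`, `logLik`,
#'   `r2_conditional`.
#' @export
fit_mixed_model <- function(table, fixed = ~ log(EE) + log(MVR),
                            response = "intensity", log_response = TRUE) {
  stopifnot("participant" %in% names(table), response %in% names(table))
  lhs <- if (log_response) sprintf("log(%s)", response) else response
  if (log_response && any(table[[response]] <= 0))
    stop("log-scale response requires strictly positive values")
  rhs <- paste(attr(stats::terms(fixed), "term.labels"), collapse = " + ")
  fml <- stats::as.formula(paste(lhs, "~", rhs, "+ (1 | participant)"))
  fit <- lmerTest::lmer(fml, data = table, REML = TRUE)
  if (lme4::isSingular(fit)) {
    vc <- lme4::VarCorr(fit)
    warning(paste0("singular mixed-model fit; variance components:\n",
                   paste(utils::capture.output(print(vc)), collapse = "\n")))
  }
  coefs <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_r <- sum(vc$vcov[vc$grp != "Residual"])
  var_e <- vc$vcov[vc$grp == "Residual"]
  var_f <- var(predict(fit, re.form = NA))
  structure(list(model = fit, coefficients = coefs,
                 AIC = AIC(fit), logLik = as.numeric(logLik(fit)),
                 r2_conditional = (var_f + var_r) / (var_f + var_r + var_e)),
            class = "mem_fit")
}

#' @export
print.mem_fit <- function(x, ...) {
  cat(sprintf("<mem_fit> AIC = %.4f | logLik = %.4f | conditional R2 = %.4f\n",
              x$AIC, x$logLik, x$r2_conditional))
  print(round(x$coefficients, 4))
  invisible(x)
}
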