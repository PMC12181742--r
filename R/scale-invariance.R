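#' Divisor-based multiscale segment levels
#'
#' Enumerates all segment durations whose sample counts divide the total
#' sample count exactly and fall between `min_level` and `max_level`
#' (inclusive), sorted descending. For a 56-s recording at 1 kHz with levels
#' between 0.002 s and 28 s this yields 54 levels.
#'
#' @param duration Recording duration in seconds.
#' @param min_level,max_level Level bounds in seconds
#'   (`min_level >= 1/sampling_rate`, `max_level <= duration/2`).
#' @param sampling_rate Sampling rate in Hz.
#' @return Numeric vector of segment durations in seconds, strictly
#'   decreasing.
#' @export
segment_levels <- function(duration, min_level, max_level, sampling_rate) {
  if (min_level < 1 / sampling_rate) stop("min_level below one sample")
  if (max_level > duration / 2) stop("max_level above half the duration")
  n_total <- round(duration * sampling_rate)
  divs <- which(n_total %% seq_len(n_total) == 0)
  lo <- min_level * sampling_rate; hi <- max_level * sampling_rate
  divs <- divs[divs >= lo - 1e-9 & divs <= hi + 1e-9]
  if (length(divs) == 0) stop("no divisor-based levels in the requested range")
  sort(divs / sampling_rate, decreasing = TRUE)
}

#' Mean fluctuation of a series at one segment level
#'
#' Partitions the series into non-overlapping segments of the level's sample
#' length, computes each segment's root-mean-square deviation around its own
#' mean, and averages across segments. A pluggable `kernel` lets a different
#' per-segment fluctuation statistic (e.g. a linearly detrended, DFA-style
#' one) be swapped in.
#'
#' @param series Numeric vector.
#' @param level_samples Segment length in samples; must divide
#'   `length(series)`.
#' @param kernel Function mapping a segment to its scalar fluctuation
#'   (default: RMS about the segment mean).
#' @return Nonnegative scalar.
#' @export
mean_fluctuation <- function(series, level_samples,
                             kernel = function(seg) sqrt(mean((seg - mean(seg))^2))) {
  n <- length(series)
  if (n %% level_samples != 0)
    stop("level must divide the series length exactly")
  segs <- matrix(series, nrow = level_samples)
  mean(apply(segs, 2, kernel))
}

#' Maximum-likelihood log-normal fit
#'
#' @param values Positive reals, at least 3.
#' @return List with `mu` (mean of logs), `sigma` (population SD of logs),
#'   and `degenerate` (`TRUE` when `sigma` is numerically 0, in which case
#'   goodness of fit is not defined).
#' @export
fit_lognormal <- function(values) {
  if (any(values <= 0)) stop("log-normal fit requires strictly positive values")
  if (length(values) < 3) stop("need at least 3 values")
  lx <- log(values)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  list(mu = mu, sigma = sigma,
       degenerate = sigma < 1e-12 * max(1, abs(mu)))
}

# Kolmogorov-Smirnov distance between the empirical CDF and a log-normal
ks_distance_lognormal <- function(values, mu, sigma) {
  xs <- sort(values); n <- length(xs)
  Fx <- plnorm(xs, meanlog = mu, sdlog = sigma)
  max(max(seq_len(n) / n - Fx), max(Fx - (seq_len(n) - 1) / n))
}

#' Parametric-bootstrap Kolmogorov-Smirnov goodness of fit
#'
#' Computes the KS distance between the sample and its fitted log-normal,
#' then draws `n_boot` synthetic samples of the same size from the fitted
#' distribution, refits the parameters for each replicate (so the null
#' distribution accounts for estimation), and reports the fraction of
#' synthetic KS statistics at least as large as the observed one.
#'
#' @param values Positive reals.
#' @param n_boot Bootstrap iterations (default 1000; fewer than 100 gives an
#'   unstable p and triggers a warning).
#' @param seed Integer seed.
#' @return List with `ks_statistic`, `p_value`, `mu`, `sigma`, `n_boot`.
#' @export
bootstrap_ks_gof <- function(values, n_boot = 1000, seed = 1L) {
  fit <- fit_lognormal(values)
  if (fit$degenerate) stop("degenerate fit (sigma = 0); goodness of fit undefined")
  if (n_boot < 100) warning("n_boot < 100 gives an unstable bootstrap p value")
  n <- length(values)
  ks_obs <- ks_distance_lognormal(values, fit$mu, fit$sigma)
  ks_boot <- with_seed(seed, {
    sims <- matrix(rlnorm(n * n_boot, meanlog = fit$mu, sdlog = fit$sigma),
                   nrow = n)
    vapply(seq_len(n_boot), function(b) {
      f <- fit_lognormal(sims[, b])
      ks_distance_lognormal(sims[, b], f$mu, f$sigma)
    }, numeric(1))
  })
  list(ks_statistic = ks_obs, p_value = mean(ks_boot >= ks_obs),
       mu = fit$mu, sigma = fit$sigma, n_boot = n_boot)
}

#' Multiscale fluctuation profile with log-normal fit
#'
#' The full scale-invariance analysis of one reconstructed dominant-mode
#' series: divisor-based segment levels, mean fluctuation per level, a
#' log-normal fit to the level-averaged fluctuations, and the bootstrapped
#' KS goodness of fit. A non-significant p value (> 0.05) indicates that
#' log-normality — an effective signature of scale-invariant, heavy-tailed
#' multiscale structure — cannot be ruled out.
#'
#' @param series Numeric vector (a sampled dominant mode).
#' @param sampling_rate Sampling rate in Hz.
#' @param min_level,max_level Level bounds in seconds.
#' @param n_boot Bootstrap iterations.
#' @param seed Integer seed.
#' @return Object of class `fluctuation_profile` with `levels` (s,
#'   descending), `mean_fluctuation`, `mu`, `sigma`, `ks_statistic`,
#'   `p_value`, `n_boot`.
#' @export
fluctuation_profile <- function(series, sampling_rate, min_level, max_level,
                                n_boot = 1000, seed = 1L) {
  levels <- segment_levels(length(series) / sampling_rate, min_level,
                           max_level, sampling_rate)
  fl <- vapply(levels, function(lv)
    mean_fluctuation(series, round(lv * sampling_rate)), numeric(1))
  gof <- bootstrap_ks_gof(fl, n_boot = n_boot, seed = seed)
  structure(list(levels = levels, mean_fluctuation = fl, mu = gof$mu,
                 sigma = gof$sigma, ks_statistic = gof$ks_statistic,
                 p_value = gof$p_value, n_boot = n_boot),
            class = "fluctuation_profile")
}

#' @export
print.fluctuation_profile <- function(x, ...) {
  cat(sprintf("<fluctuation_profile> %d levels [%g, %g] s | lognormal mu=%.4f sigma=%.4f | KS GOF=%.4f p=%.4f\n",
              length(x$levels), min(x$levels), max(x$levels), x$mu, x$sigma,
              x$ks_statistic, x$p_value))
  invisible(x)
}
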