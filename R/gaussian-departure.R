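#' Kurtosis coefficient of pooled window scores
#'
#' Fourth central moment divided by the squared variance (non-excess
#' convention: a Gaussian sample gives 3, and 1 is the universal lower
#' bound).
#'
#' @param scores Numeric vector of projection scores pooled over
#'   participants and channels; at least 8 values.
#' @return Scalar kurtosis coefficient.
#' @export
window_kurtosis <- function(scores) {
  if (length(scores) < 8) stop("need at least 8 scores per window")
  m <- mean(scores)
  v <- mean((scores - m)^2)
  if (v <= 0) stop("zero variance; kurtosis undefined")
  mean((scores - m)^4) / v^2
}

#' Per-window kurtosis series of a turbulence field
#'
#' For each condition, the kurtosis coefficient of every window's projection
#' scores pooled across participants and channels.
#'
#' @param field A `turbulence_field`.
#' @return Data frame with columns `condition`, `window`, `kurtosis`.
#' @export
kurtosis_series <- function(field) {
  stopifnot(inherits(field, "turbulence_field"))
  d <- dim(field$xi)
  kurt <- matrix(NA_real_, d[3], d[2])
  for (j in seq_len(d[2])) for (l in seq_len(d[3]))
    kurt[l, j] <- window_kurtosis(as.vector(field$xi[, j, l, ]))
  data.frame(condition = rep(field$conditions, each = d[3]),
             window = rep(seq_len(d[3]), d[2]),
             kurtosis = as.vector(kurt))
}

#' Kozachenko-Leonenko nearest-neighbour differential entropy (1-D)
#'
#' @param x Numeric sample (more than `k` points).
#' @param k Neighbour order (default 3).
#' @return Differential entropy estimate in nats.
#' @export
kl_entropy <- function(x, k = 3) {
  n <- length(x)
  if (n <= k) stop("need more than k points for the entropy estimate")
  xs <- sort(x)
  eps <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - k); hi <- min(n, i + k)
    d <- abs(xs[lo:hi] - xs[i])
    sort(d[d >= 0])[k + 1]  # k-th neighbour, skipping the point itself
  }, numeric(1))
  digamma(n) - digamma(k) + mean(log(2 * pmax(eps, .Machine$double.eps)))
}

#' Split scorers for the entropic threshold scan
#'
#' Given the left/right subsets of a candidate split and the pooled-sample
#' entropy, return a score where higher means a better split.
#' `enid_score_gain` is the normalized entropy gain (pooled entropy minus
#' the size-weighted subset entropies); `enid_score_absdiff` is the
#' normalized absolute entropy difference between the subsets.
#'
#' @param left,right Numeric subsets on either side of the split.
#' @param h_all Pooled-sample differential entropy.
#' @param k Neighbour order of the entropy estimator.
#' @return Scalar score.
#' @export
enid_score_gain <- function(left, right, h_all, k = 3) {
  n <- length(left) + length(right)
  h_split <- (length(left) * kl_entropy(left, k) +
                length(right) * kl_entropy(right, k)) / n
  (h_all - h_split) / max(abs(h_all), .Machine$double.eps)
}

#' @rdname enid_score_gain
#' @export
enid_score_absdiff <- function(left, right, h_all, k = 3) {
  abs(kl_entropy(left, k) - kl_entropy(right, k)) /
    max(abs(h_all), .Machine$double.eps)
}

#' Entropic split threshold for departure from Gaussianity
#'
#' Locates the kurtosis value at which window kurtosis coefficients separate
#' into a near-Gaussian regime (values attracted to the vicinity of 3) and a
#' turbulent, heavy-tailed regime. Coefficients (all > 3) are mapped to their
#' inverses, every admissible split of the sorted inverses (at least
#' `min_size` points per side) is scored by a normalized entropic distance
#' built on Kozachenko-Leonenko nearest-neighbour differential entropies,
#' and the best split — the one whose two subsets are closest to
#' statistically independent, i.e. whose split removes the most joint
#' entropy — is mapped back to the kurtosis scale. The default scorer is the
#' normalized entropy gain of the split; `scorer` is pluggable (e.g.
#' `enid_score_absdiff` for a normalized entropy difference).
#'
#' @param coefficients Kurtosis coefficients; only values > 3 enter the
#'   scan, and at least 30 are required.
#' @param min_size Minimum subset size per side (default 10, keeping the
#'   entropy estimates defined).
#' @param k Nearest-neighbour order of the entropy estimator (default 3).
#' @param scorer Split-scoring function `(left, right, h_all, k)`.
#' @return List of class `enid_result`: `threshold` (> 3), `score`, and
#'   `n_used`.
#' @export
enid_threshold <- function(coefficients, min_size = 10, k = 3,
                           scorer = enid_score_gain) {
  vals <- coefficients[coefficients > 3]
  if (length(vals) < 30) stop("need at least 30 coefficients > 3")
  y <- sort(1 / vals)
  n <- length(y)
  h_all <- kl_entropy(y, k)
  cuts <- seq(min_size, n - min_size)
  scores <- vapply(cuts, function(ci)
    scorer(y[seq_len(ci)], y[(ci + 1):n], h_all, k), numeric(1))
  best <- cuts[which.max(scores)]
  split_y <- (y[best] + y[best + 1]) / 2
  structure(list(threshold = 1 / split_y, score = max(scores),
                 n_used = n), class = "enid_result")
}

#' Per-condition exceedance proportions
#'
#' Fraction of windows whose kurtosis coefficient exceeds the threshold, per
#' condition.
#'
#' @param series Data frame from [kurtosis_series()] (columns `condition`,
#'   `kurtosis`).
#' @param threshold Finite kurtosis threshold.
#' @return Named numeric vector of proportions in `[0, 1]`.
#' @export
exceedance_proportions <- function(series, threshold) {
  stopifnot(is.finite(threshold), nrow(series) > 0)
  tapply(series$kurtosis > threshold, series$condition, mean)[
    unique(series$condition)]
}
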