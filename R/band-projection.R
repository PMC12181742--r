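#' Zero-phase Butterworth band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass of the given
#' order to each channel.
#'
#' @param x Numeric matrix (channels x samples) or vector.
#' @param low,high Band edges in Hz, `0 < low < high < sampling_rate / 2`.
#' @param order Filter order of the underlying design (default 4).
#' @param sampling_rate Sampling rate in Hz.
#' @return Filtered data, same shape as `x`.
#' @export
butterworth_bandpass <- function(x, low, high, order = 4, sampling_rate) {
  if (!(low > 0 && low < high && high < sampling_rate / 2))
    stop("band edges must satisfy 0 < low < high < sampling_rate/2")
  bf <- signal::butter(order, c(low, high) / (sampling_rate / 2), type = "pass")
  if (is.matrix(x)) {
    t(apply(x, 1, function(row) signal::filtfilt(bf, row)))
  } else {
    signal::filtfilt(bf, x)
  }
}

# zero-phase Butterworth band-stop, used for the SSD flanking-noise signal
butterworth_bandstop <- function(x, low, high, order = 4, sampling_rate) {
  bf <- signal::butter(order, c(low, high) / (sampling_rate / 2), type = "stop")
  if (is.matrix(x)) t(apply(x, 1, function(row) signal::filtfilt(bf, row)))
  else signal::filtfilt(bf, x)
}

#' Spatio-spectral decomposition (SSD)
#'
#' Finds spatial filters maximizing power in a target frequency band relative
#' to the flanking bands, by solving the generalized eigenproblem between the
#' band-filtered covariance and the flanking-noise covariance. The signal
#' covariance comes from a band-pass at `[low - signal_margin, high +
#' signal_margin]`; the noise covariance from a band-pass at
#' `[low - noise_bandpass_margin, high + noise_bandpass_margin]` followed by a
#' band-stop at `[low - noise_bandstop_margin, high + noise_bandstop_margin]`,
#' so the flanks occupy the bins neighbouring the band on either side.
#' Covariances are averaged over the full recording. A rank-deficient noise
#' covariance is floored (regularized) with a warning.
#'
#' @param x Channels x samples matrix (broadband).
#' @param low,high Target band edges in Hz.
#' @param sampling_rate Sampling rate in Hz.
#' @param signal_margin,noise_bandpass_margin,noise_bandstop_margin Margins in
#'   Hz (defaults 2, 4, 1).
#' @return An object of class `ssd_result` with `filters` (K x K, columns
#'   sorted by eigenvalue descending), `patterns` (K x K), `eigenvalues`, and
#'   `n_selected` chosen by [perpendicular_line_select()].
#' @export
ssd_decompose <- function(x, low, high, sampling_rate, signal_margin = 2,
                          noise_bandpass_margin = 4, noise_bandstop_margin = 1) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  if (low - noise_bandpass_margin <= 0 ||
      high + noise_bandpass_margin >= sampling_rate / 2)
    stop("band plus margins must lie strictly inside (0, Nyquist)")
  x_sig <- butterworth_bandpass(x, low - signal_margin, high + signal_margin,
                                sampling_rate = sampling_rate)
  x_noise <- butterworth_bandpass(x, low - noise_bandpass_margin,
                                  high + noise_bandpass_margin,
                                  sampling_rate = sampling_rate)
  x_noise <- butterworth_bandstop(x_noise, low - noise_bandstop_margin,
                                  high + noise_bandstop_margin,
                                  sampling_rate = sampling_rate)
  Cs <- cov(t(x_sig)); Cn <- cov(t(x_noise))
  en <- eigen((Cn + t(Cn)) / 2, symmetric = TRUE)
  if (min(en$values) < 1e-10 * max(en$values))
    warning("rank-deficient noise covariance; applying eigenvalue flooring")
  f <- sym_inv_sqrt(Cn)
  Mm <- f$inv_sqrt %*% Cs %*% f$inv_sqrt
  em <- eigen((Mm + t(Mm)) / 2, symmetric = TRUE)
  W <- f$inv_sqrt %*% em$vectors
  W <- apply(W, 2, canon_sign)
  # spatial patterns: project the signal covariance through the filters
  P <- Cs %*% W %*% solve(t(W) %*% Cs %*% W)
  structure(list(filters = W, patterns = P, eigenvalues = em$values,
                 n_selected = perpendicular_line_select(em$values),
                 band = c(low, high)),
            class = "ssd_result")
}

#' Low-rank SSD reconstruction of a band-limited signal
#'
#' Backprojects the first `n` SSD components of the band-filtered signal,
#' yielding a spatially denoised channels x samples matrix.
#'
#' @param ssd An `ssd_result`.
#' @param x_band Band-filtered channels x samples matrix (the same band the
#'   decomposition was computed for).
#' @param n Number of components to keep (default `ssd$n_selected`).
#' @return Denoised channels x samples matrix.
#' @export
ssd_denoise <- function(ssd, x_band, n = ssd$n_selected) {
  stopifnot(inherits(ssd, "ssd_result"), n >= 1, n <= ncol(ssd$filters))
  idx <- seq_len(n)
  ssd$patterns[, idx, drop = FALSE] %*%
    (t(ssd$filters[, idx, drop = FALSE]) %*% x_band)
}

#' Scree elbow selection by the perpendicular line method
#'
#' Given eigenvalues sorted in descending order, draws the straight line
#' joining the first and last scree points and locates the point with maximum
#' perpendicular distance to it — the elbow, i.e. the first point of the
#' scree floor. The retained component count is one less than that index
#' (the components before the drop). Collinear screes, ties, and screes with
#' fewer than 3 points return 1 (tie broken toward fewest components).
#'
#' @param eigenvalues Numeric vector, sorted non-increasing.
#' @return Integer count of retained components (>= 1).
#' @export
perpendicular_line_select <- function(eigenvalues) {
  n <- length(eigenvalues)
  if (n < 3) return(1L)
  if (is.unsorted(rev(eigenvalues) + 1e-12 * max(abs(eigenvalues))))
    stop("eigenvalues must be sorted in descending order")
  a <- c(1, eigenvalues[1]); b <- c(n, eigenvalues[n])
  d <- b - a
  dist <- vapply(seq_len(n), function(i) {
    v <- c(i, eigenvalues[i]) - a
    abs(v[1] * d[2] - v[2] * d[1]) / sqrt(sum(d^2))
  }, numeric(1))
  if (max(dist) <= 1e-12 * max(1, abs(eigenvalues[1]))) return(1L)
  max(1L, which.max(dist) - 1L)
}

#' Dominant spatial direction under a Cauchy likelihood
#'
#' Estimates the dominant spatial component of a multichannel signal robustly,
#' by iteratively reweighted eigendecomposition: samples are weighted by
#' `1 / (1 + (r/gamma)^2)` where `r` is the norm of the sample's residual
#' orthogonal to the current direction and `gamma` is a median-absolute-
#' deviation scale, the Cauchy-likelihood analogue of the Gaussian dominant
#' eigenvector. Iteration stops when the direction changes by less than
#' `tol` radians or after `max_iter` sweeps (then the best iterate is
#' returned with `converged = FALSE` and a warning).
#'
#' @param x Channels x samples matrix, at least 2 channels.
#' @param max_iter,tol Iteration controls (defaults 200 and 1e-6 rad).
#' @return An object of class `band_projection` with `dominant_direction`
#'   (unit norm, largest-magnitude entry positive), `projected` (the rank-1
#'   backprojection `v (v' x)`, channels x samples), `converged`, and
#'   `n_iter`.
#' @export
cauchy_pca_dominant <- function(x, max_iter = 200, tol = 1e-6) {
  stopifnot(is.matrix(x), nrow(x) >= 2, ncol(x) > nrow(x))
  xc <- x - rowMeans(x)
  v <- canon_sign(eigen(cov(t(xc)), symmetric = TRUE)$vectors[, 1])
  converged <- FALSE; it <- 0
  for (it in seq_len(max_iter)) {
    scores <- drop(crossprod(v, xc))
    resid <- xc - tcrossprod(v, scores)
    r <- sqrt(colSums(resid^2))
    if (max(r) < 1e-12 * max(abs(scores), 1)) { converged <- TRUE; break }
    gamma <- max(mad(r, center = median(r)), 1e-3 * median(r),
                 .Machine$double.eps)
    w <- 1 / (1 + (r / gamma)^2)
    Cw <- (xc * rep(w, each = nrow(xc))) %*% t(xc) / sum(w)
    v_new <- canon_sign(eigen((Cw + t(Cw)) / 2, symmetric = TRUE)$vectors[, 1])
    ang <- acos(min(1, abs(sum(v * v_new))))
    v <- v_new
    if (ang < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("Cauchy PCA did not converge; returning best iterate")
  structure(list(dominant_direction = v,
                 projected = tcrossprod(v, drop(crossprod(v, xc))),
                 converged = converged, n_iter = it),
            class = "band_projection")
}

#' Band-limited, spatially denoised projection of a dataset
#'
#' The per-recording front end of the turbulence pipeline: each participant x
#' condition recording is band-pass filtered, spatially denoised by the
#' low-rank SSD reconstruction, and reduced to its rank-1 backprojection onto
#' the Cauchy-PCA dominant direction (channels are preserved).
#'
#' @param dataset An `eeg_dataset`.
#' @param low,high Band edges in Hz. The conventional presets are alpha
#'   (8-13 Hz) and high gamma (50-80 Hz).
#' @param use_ssd Apply the SSD denoising step (default `TRUE`; disable for
#'   few-channel synthetic data where flanking covariances are singular).
#' @param ... Further arguments passed to [ssd_decompose()].
#' @return A new `eeg_dataset` whose `data` holds the projected recordings;
#'   the band is recorded in the `band` element.
#' @export
band_project <- function(dataset, low, high, use_ssd = TRUE, ...) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  d <- dim(dataset$data)
  fs <- dataset$sampling_rate
  out <- dataset
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    x <- dataset$data[i, j, , ]
    xb <- butterworth_bandpass(x, low, high, sampling_rate = fs)
    if (use_ssd) {
      dec <- ssd_decompose(x, low, high, sampling_rate = fs, ...)
      xb <- ssd_denoise(dec, xb)
    }
    out$data[i, j, , ] <- cauchy_pca_dominant(xb)$projected
  }
  out$band <- c(low, high)
  out
}
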