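# Small synthetic datasets and independent oracles shared across test files.

# reduced-scale recording set with the generator's statistical structure
small_config <- function(N = 3, J = 2, K = 6, fs = 250, duration = 4,
                         snr = 2, ...) {
  simulation_config(n_participants = N, n_conditions = J, n_channels = K,
                    sampling_rate = fs, duration = duration, snr = snr, ...)
}

# wrap a raw participants x conditions x channels x samples array
as_dataset <- function(dat, fs) {
  d <- dim(dat)
  structure(list(data = dat, sampling_rate = fs,
                 participants = seq_len(d[1]),
                 conditions = paste0("cond", seq_len(d[2])),
                 channels = paste0("ch", seq_len(d[3]))),
            class = "eeg_dataset")
}

# fraction of spectral power inside [low, high], by FFT periodogram
band_power_ratio <- function(x, low, high, fs) {
  ratios <- apply(x, 1, function(ch) {
    n <- length(ch)
    P <- Mod(stats::fft(ch))^2
    f <- (0:(n - 1)) * fs / n
    half <- f <= fs / 2
    sum(P[half & f >= low & f <= high]) / sum(P[half])
  })
  w <- rowSums(x^2)
  sum(ratios * w) / sum(w)
}

# dense-grid oracle for the kurtosis-operator spectrum: evaluates the
# whitened curves on a fine grid, forms the empirical fourth-moment kernel
# with trapezoid quadrature, and eigendecomposes the discretized operator.
# Returns eigenvalues sorted descending (nonzero part).
oracle_kurtosis_eigvals <- function(A_white, basis, J, n_grid = 2000) {
  p <- basis$p
  tg <- seq(basis$domain[1], basis$domain[2], length.out = n_grid)
  B <- eval_basis(basis, tg)
  wq <- c(0.5, rep(1, n_grid - 2), 0.5) * (tg[2] - tg[1])
  Xs <- lapply(seq_len(J), function(j)
    A_white[, ((j - 1) * p + 1):(j * p)] %*% t(B))
  D <- Reduce(`+`, lapply(Xs, function(x) (x^2) %*% wq))  # squared L2 norms
  bigX <- do.call(cbind, Xs)                              # n x (J * n_grid)
  Wq <- rep(wq, J)
  n <- nrow(bigX)
  # nonzero eigenvalues of the kernel-times-quadrature operator equal those
  # of the small n x n matrix D^{1/2} X diag(Wq) X' D^{1/2} / n
  Xd <- bigX * as.numeric(sqrt(D))
  S <- Xd %*% (Wq * t(Xd)) / n
  sort(eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

# exact signed-rank reference by full sign enumeration (no zeros/ties)
enumerate_signed_rank <- function(d) {
  n <- length(d)
  rk <- rank(abs(d))
  W_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- signs %*% rk
  p_lower <- mean(W_all <= W_obs)
  p_upper <- mean(W_all >= W_obs)
  list(W = W_obs, p = min(1, 2 * min(p_lower, p_upper)))
}

# brute-force Friedman statistic from hand-computed within-row ranks
brute_force_friedman <- function(mat) {
  ranks <- t(apply(mat, 1, rank))
  N <- nrow(mat); J <- ncol(mat)
  Rj <- colSums(ranks)
  12 / (N * J * (J + 1)) * sum(Rj^2) - 3 * N * (J + 1)
}
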