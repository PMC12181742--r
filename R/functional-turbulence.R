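#' Sliding-window grid
#'
#' Half-open windows `[start, start + window_length)` in milliseconds, with
#' starts at `0, hop, 2 hop, ...` while the window fits inside the recording;
#' trailing samples not covered by a full window are dropped.
#'
#' @param duration Recording duration in ms.
#' @param window_length Window length in ms.
#' @param hop Hop size in ms (default 20, the scale of interneuronal
#'   transmission latencies).
#' @return Object of class `window_grid` with `starts` (ms), `window_length`,
#'   `hop`, and `tau` (window count).
#' @export
make_windows <- function(duration, window_length, hop = 20) {
  if (!(hop > 0 && hop <= window_length)) stop("need 0 < hop <= window_length")
  if (window_length > duration) stop("window longer than recording")
  starts <- seq(0, duration - window_length, by = hop)
  structure(list(starts = starts, window_length = window_length, hop = hop,
                 duration = duration, tau = length(starts)),
            class = "window_grid")
}

#' Spectral resolution of an analysis window
#'
#' The frequency resolution implied by a finite window is the reciprocal of
#' its duration: a 500-ms window resolves 2 Hz (enough to distinguish
#' oscillations within the narrow alpha band) and a 100-ms window resolves
#' 10 Hz (trading resolution for the temporal precision the faster gamma
#' dynamics require).
#'
#' @param window_length Window length in ms.
#' @return Resolution in Hz.
#' @export
window_resolution_hz <- function(window_length) {
  stopifnot(window_length > 0)
  1000 / window_length
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("<window_grid> %d windows of %g ms, hop %g ms over %g ms\n",
              x$tau, x$window_length, x$hop, x$duration))
  invisible(x)
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch)
gauss_legendre <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  Jm <- diag(0, n)
  Jm[cbind(i, i + 1)] <- b; Jm[cbind(i + 1, i)] <- b
  e <- eigen(Jm, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

#' B-spline basis with exact Gram matrix
#'
#' Constructs a B-spline basis of dimension `p` and order `order` (degree
#' `order - 1`) on `domain`, with equally spaced interior knots and full-
#' multiplicity end knots. The Gram matrix of pairwise \eqn{L^2} inner
#' products is computed by per-interval Gauss-Legendre quadrature with
#' `order` nodes, exact for the piecewise-polynomial products.
#'
#' @param p Basis dimension (`p >= order`).
#' @param order Spline order (default 4, cubic).
#' @param domain Length-2 numeric, the interval.
#' @return Object of class `bspline_basis` with `p`, `order`, `knots`,
#'   `domain`, and `gram` (p x p).
#' @export
bspline_basis <- function(p, order = 4, domain = c(0, 1)) {
  stopifnot(p >= order, domain[2] > domain[1])
  n_int <- p - order
  inner <- if (n_int > 0)
    seq(domain[1], domain[2], length.out = n_int + 2)[-c(1, n_int + 2)]
  else numeric(0)
  knots <- c(rep(domain[1], order), inner, rep(domain[2], order))
  gl <- gauss_legendre(order)
  brk <- c(domain[1], inner, domain[2])
  G <- matrix(0, p, p)
  for (q in seq_len(length(brk) - 1)) {
    mid <- (brk[q] + brk[q + 1]) / 2; half <- (brk[q + 1] - brk[q]) / 2
    tq <- mid + half * gl$x
    Bq <- splineDesign(knots, tq, ord = order)
    G <- G + crossprod(Bq * sqrt(half * gl$w))
  }
  structure(list(p = p, order = order, knots = knots, domain = domain,
                 gram = G), class = "bspline_basis")
}

#' Evaluate a B-spline basis at given times
#'
#' @param basis A [bspline_basis()].
#' @param times Numeric vector inside the basis domain.
#' @return Matrix `length(times) x p` of basis values.
#' @export
eval_basis <- function(basis, times) {
  stopifnot(inherits(basis, "bspline_basis"))
  splineDesign(basis$knots, times, ord = basis$order,
               outer.ok = FALSE)
}

#' Least-squares basis expansion of windowed curves
#'
#' Fits every curve (row) by ordinary least squares on the B-spline design
#' evaluated at the sampling times, per condition, and assembles the
#' concatenated coefficient matrix together with the block-diagonal Gram
#' matrix of the condition-stacked basis system.
#'
#' @param curves A curves x timepoints matrix (one condition) or a list of
#'   such matrices, one per condition, all sharing the time grid.
#' @param times Sampling times (length = timepoints) inside the window.
#' @param p Basis dimension; `timepoints >= p >= order`.
#' @param order Spline order (default 4).
#' @param basis Optionally a prebuilt [bspline_basis()] spanning
#'   `range(times)`; `p`/`order` are then ignored.
#' @return Object of class `basis_model`: `basis`, `A_list` (per-condition
#'   coefficient matrices, curves x p), `A` (curves x pJ concatenation),
#'   `G` (pJ x pJ block-diagonal Gram), `J`, `rmse` (per curve, per
#'   condition), `times`.
#' @export
fit_basis <- function(curves, times, p = 8, order = 4, basis = NULL) {
  if (is.matrix(curves)) curves <- list(curves)
  stopifnot(length(times) == ncol(curves[[1]]))
  if (is.null(basis)) {
    if (length(times) < p) stop("need at least p timepoints in the window")
    basis <- bspline_basis(p, order, range(times))
  }
  p <- basis$p
  B <- eval_basis(basis, times)
  kap <- kappa(crossprod(B), exact = FALSE)
  if (!is.finite(kap) || kap > 1e10)
    stop(sprintf("ill-conditioned basis design (condition number %.3g); reduce p",
                 kap))
  qrB <- qr(B)
  J <- length(curves)
  A_list <- vector("list", J); rmse <- vector("list", J)
  for (j in seq_len(J)) {
    A_list[[j]] <- t(qr.coef(qrB, t(curves[[j]])))
    fitted <- A_list[[j]] %*% t(B)
    rmse[[j]] <- sqrt(rowMeans((curves[[j]] - fitted)^2))
  }
  G <- kronecker(diag(J), basis$gram)
  structure(list(basis = basis, A_list = A_list,
                 A = do.call(cbind, A_list), G = G, J = J,
                 rmse = rmse, times = times),
            class = "basis_model")
}

#' ZCA whitening of basis coefficients in the Gram metric
#'
#' Maps the coefficient matrix `A` so that the whitened representation
#' `A_white %*% G^{1/2}` has identity sample covariance, using the symmetric
#' (ZCA) inverse square root of the sample covariance of `A %*% G^{1/2}`.
#' Covariance eigenvalues are floored at `floor_frac` of the largest;
#' optional spectral truncation (`rank`) is available but off by default.
#'
#' @param A Curves x pJ coefficient matrix (more curves than columns).
#' @param G pJ x pJ Gram matrix (symmetric positive definite).
#' @param floor_frac Relative eigenvalue floor (default 1e-10).
#' @param rank Optional spectral truncation rank (`NULL` = full).
#' @return List with `A_white`, `center` (column means of `A G^{1/2}`), and
#'   the factors `G_half`, `G_inv_half`, `C_half`, `C_inv_half` needed to
#'   invert the transform.
#' @export
whiten_coefficients <- function(A, G, floor_frac = 1e-10, rank = NULL) {
  stopifnot(ncol(A) == nrow(G))
  if (nrow(A) <= ncol(A))
    stop("fewer curves than coefficients; reduce basis dimension p or apply spectral truncation")
  gf <- sym_inv_sqrt(G)
  Z <- A %*% gf$sqrt
  center <- colMeans(Z)
  Zc <- sweep(Z, 2, center)
  C <- cov(Zc)
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (!is.null(rank)) {
    keep <- seq_len(min(rank, ncol(A)))
    lam <- ev$values; lam[-keep] <- Inf  # truncated directions are zeroed
    w_inv <- ev$vectors[, keep] %*% (t(ev$vectors[, keep]) / sqrt(lam[keep]))
    w_fwd <- ev$vectors[, keep] %*% (t(ev$vectors[, keep]) * sqrt(lam[keep]))
  } else {
    lam <- pmax(ev$values, floor_frac * max(ev$values))
    w_inv <- ev$vectors %*% (t(ev$vectors) / sqrt(lam))
    w_fwd <- ev$vectors %*% (t(ev$vectors) * sqrt(lam))
  }
  list(A_white = Zc %*% w_inv %*% gf$inv_sqrt, center = center,
       G_half = gf$sqrt, G_inv_half = gf$inv_sqrt,
       C_half = w_fwd, C_inv_half = w_inv)
}

#' Kurtosis matrix of whitened coefficients
#'
#' With `W = A_white %*% G^{1/2}` (identity covariance) and the diagonal
#' weight `D = diag(W W')` of squared row norms in the Gram metric, the
#' kurtosis matrix is `Sigma = W' D W / n`, the coefficient-space kernel of
#' the kurtosis operator: it quantifies fourth-moment fluctuations of the
#' functional data. For whitened Gaussian data in dimension d its spectrum
#' concentrates at d + 2.
#'
#' @param A_white Whitened coefficient matrix (from
#'   [whiten_coefficients()]).
#' @param G Gram matrix.
#' @return List with `Sigma` (pJ x pJ, symmetric PSD) and `D` (vector of
#'   diagonal weights).
#' @export
kurtosis_matrix <- function(A_white, G) {
  stopifnot(ncol(A_white) == nrow(G))
  gf <- sym_inv_sqrt(G)
  W <- A_white %*% gf$sqrt
  D <- rowSums(W^2)
  Sigma <- crossprod(W, D * W) / nrow(W)
  list(Sigma = (Sigma + t(Sigma)) / 2, D = D)
}

#' Eigendecomposition of the kurtosis operator
#'
#' Solves the kurtosis-operator eigenproblem in coefficient space. In the
#' Gram metric the operator reduces to the symmetric matrix `Sigma`, whose
#' eigenvectors `u_s`, corrected by `G^{-1/2}`, give the eigenfunction
#' coefficients: `psi_s(t) = phi(t)' G^{-1/2} u_s`. Eigenfunctions have unit
#' L2 norm and are pairwise orthogonal; eigenvalues are returned in
#' descending order and signs are canonicalized (largest-magnitude
#' coefficient positive).
#'
#' @param Sigma Kurtosis matrix (pJ x pJ).
#' @param G Gram matrix (pJ x pJ).
#' @return Object of class `kurtosis_spectrum` with `values` (kappa,
#'   descending), `b` (columns = eigenvectors of `Sigma`), and `psi_coef`
#'   (columns = eigenfunction coefficients `G^{-1/2} u_s` in the stacked
#'   basis).
#' @export
kurtosis_eigen <- function(Sigma, G) {
  stopifnot(nrow(Sigma) == nrow(G), ncol(Sigma) == nrow(Sigma))
  ee <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  gf <- sym_inv_sqrt(G)
  psi <- gf$inv_sqrt %*% ee$vectors
  for (s in seq_len(ncol(psi))) {
    ps <- canon_sign(psi[, s])
    if (!identical(ps, psi[, s])) ee$vectors[, s] <- -ee$vectors[, s]
    psi[, s] <- ps
  }
  structure(list(values = ee$values, b = ee$vectors, psi_coef = psi,
                 G = G), class = "kurtosis_spectrum")
}

#' Split a stacked eigenfunction into per-condition components
#'
#' The dominant eigenfunction lives in the condition-stacked basis of
#' dimension pJ; partitioning its coefficient vector (already carrying the
#' `G^{-1/2}` correction) into J consecutive blocks of p and expanding each
#' block in the shared basis yields the condition-embedded components
#' `psi_1j`. The squared norms of the blocks partition the unit norm of the
#' full eigenfunction.
#'
#' @param psi_coef Coefficient vector of length `p * J`.
#' @param p Basis dimension per condition.
#' @param J Number of conditions.
#' @return List of J coefficient vectors of length p.
#' @export
split_condition_modes <- function(psi_coef, p, J) {
  if (length(psi_coef) != p * J)
    stop("coefficient length is not p * J")
  lapply(seq_len(J), function(j) psi_coef[((j - 1) * p + 1):(j * p)])
}

#' Projection scores of condition curves onto a condition mode
#'
#' Computes the inner products `int X(t) psi_1j(t) dt` in coefficient space
#' as `A_j %*% G_phi %*% c_j`, where `c_j` is the mode's coefficient block.
#'
#' @param A_j Curves x p coefficient matrix of the condition's curves.
#' @param G_phi p x p Gram matrix of the shared basis.
#' @param mode_coef Coefficient vector (length p) of the condition mode.
#' @return Numeric vector of scores, one per curve.
#' @export
project_scores <- function(A_j, G_phi, mode_coef) {
  if (ncol(A_j) != nrow(G_phi) || length(mode_coef) != ncol(G_phi))
    stop("basis mismatch between coefficients, Gram matrix and mode")
  drop(A_j %*% (G_phi %*% mode_coef))
}

#' Sliding-window turbulence field
#'
#' Runs the full per-window computation on a (band-projected) dataset: basis
#' expansion of all participant x channel curves per condition, ZCA
#' whitening in the Gram metric, kurtosis-matrix eigendecomposition,
#' condition split of the dominant eigenfunction, and projection scores.
#' Eigenfunction signs are aligned across consecutive windows (the dominant
#' mode is flipped whenever its coefficient inner product with the previous
#' window's mode is negative), making adjacent-window differences — and
#' hence turbulence intensity — well defined.
#'
#' @param dataset An `eeg_dataset` (typically the output of
#'   [band_project()]).
#' @param window_length Window length in ms (500 for alpha-scale, 100 for
#'   gamma-scale analyses).
#' @param hop Hop in ms (default 20).
#' @param p Basis dimension per condition (default 8).
#' @param order Spline order (default 4).
#' @return Object of class `turbulence_field` with `xi` (array participants
#'   x conditions x tau x channels), `grid`, `kappa` (dominant eigenvalue per
#'   window), `modes` (tau x pJ matrix of aligned dominant-eigenfunction
#'   coefficients), `basis`, and labels.
#' @export
turbulence_field <- function(dataset, window_length, hop = 20, p = 8,
                             order = 4) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  d <- dim(dataset$data)
  N <- d[1]; J <- d[2]; K <- d[3]; M <- d[4]
  fs <- dataset$sampling_rate
  duration_ms <- M / fs * 1000
  grid <- make_windows(duration_ms, window_length, hop)
  if (grid$tau < 2) stop("need at least 2 windows (tau >= 2)")
  w <- round(window_length / 1000 * fs)
  times <- (seq_len(w) - 1) / fs
  basis <- bspline_basis(p, order, range(times))
  G_phi <- basis$gram
  xi <- array(NA_real_, dim = c(N, J, grid$tau, K))
  kappa1 <- numeric(grid$tau)
  modes <- matrix(NA_real_, grid$tau, p * J)
  prev <- NULL
  for (l in seq_len(grid$tau)) {
    i0 <- round(grid$starts[l] / 1000 * fs)
    idx <- (i0 + 1):(i0 + w)
    res <- tryCatch({
      curves <- lapply(seq_len(J), function(j)
        matrix(dataset$data[, j, , idx], N * K, w))
      bm <- fit_basis(curves, times, basis = basis)
      wh <- whiten_coefficients(bm$A, bm$G)
      km <- kurtosis_matrix(wh$A_white, bm$G)
      sp <- kurtosis_eigen(km$Sigma, bm$G)
      list(bm = bm, sp = sp)
    }, error = function(e)
      stop(sprintf("window %d failed: %s", l, conditionMessage(e)),
           call. = FALSE))
    cvec <- res$sp$psi_coef[, 1]
    if (!is.null(prev) && sum(cvec * prev) < 0) cvec <- -cvec
    modes[l, ] <- cvec
    prev <- cvec
    kappa1[l] <- res$sp$values[1]
    blocks <- split_condition_modes(cvec, p, J)
    for (j in seq_len(J)) {
      s <- project_scores(res$bm$A_list[[j]], G_phi, blocks[[j]])
      xi[, j, l, ] <- matrix(s, N, K)
    }
  }
  structure(list(xi = xi, grid = grid, kappa = kappa1, modes = modes,
                 basis = basis, p = p, J = J,
                 participants = dataset$participants,
                 conditions = dataset$conditions,
                 band = dataset$band),
            class = "turbulence_field")
}

#' @export
print.turbulence_field <- function(x, ...) {
  d <- dim(x$xi)
  cat(sprintf("<turbulence_field> %d participants x %d conditions, tau = %d windows, K = %d channels\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Turbulence intensity of a score field
#'
#' The mean squared Euclidean difference between adjacent window score
#' vectors: `mean_l || xi_l - xi_{l+1} ||^2`. Zero if and only if all
#' adjacent score vectors are equal; for a K-dimensional random walk with
#' i.i.d. per-coordinate step variance `sigma^2` it converges to
#' `K * sigma^2`.
#'
#' @param xi A tau x K matrix of window score vectors, or a
#'   `turbulence_field` (then a per participant x condition table is
#'   returned).
#' @param ... Unused.
#' @return A scalar for a matrix input; for a `turbulence_field`, a
#'   `data.frame` with `participant`, `condition`, `band`, `intensity`.
#' @export
turbulence_intensity <- function(xi, ...) UseMethod("turbulence_intensity")

#' @export
turbulence_intensity.default <- function(xi, ...) {
  xi <- as.matrix(xi)
  if (nrow(xi) < 2) stop("need at least 2 windows (tau >= 2)")
  dif <- diff(xi)
  mean(rowSums(dif^2))
}

#' @export
turbulence_intensity.turbulence_field <- function(xi, ...) {
  field <- xi
  d <- dim(field$xi)
  out <- expand.grid(participant = field$participants,
                     condition = field$conditions,
                     stringsAsFactors = FALSE)
  out$band <- if (is.null(field$band)) NA_character_ else
    paste0(field$band[1], "-", field$band[2], "Hz")
  out$intensity <- NA_real_
  for (r in seq_len(nrow(out))) {
    i <- match(out$participant[r], field$participants)
    j <- match(out$condition[r], field$conditions)
    out$intensity[r] <- turbulence_intensity(field$xi[i, j, , ])
  }
  out
}

#' Write a turbulence intensity table as CSV
#'
#' @param table Data frame with columns `participant,condition,band,intensity`.
#' @param path Output file path.
#' @export
write_intensity_csv <- function(table, path) {
  stopifnot(all(c("participant", "condition", "band", "intensity") %in%
                  names(table)))
  write.csv(table[, c("participant", "condition", "band", "intensity")], path,
            row.names = FALSE)
  invisible(path)
}

#' Gaussian overlap-add reconstruction of windowed modes
#'
#' Stitches per-window mode evaluations into one continuous series by
#' overlap-add with a Gaussian taper of standard deviation
#' `window_samples / width_factor`, normalized pointwise by the summed taper
#' weights (so constant window modes reconstruct exactly). Windows are
#' assumed to start every `hop_samples` samples (default: half the window,
#' the reconstruction hop).
#'
#' @param window_modes Matrix (windows x window_samples): each row is the
#'   mode evaluated on that window's sample grid.
#' @param hop_samples Hop between window starts in samples (default half the
#'   window length).
#' @param width_factor Taper width factor (default 4).
#' @return Numeric vector covering the span of the windows.
#' @export
reconstruct_mode <- function(window_modes, hop_samples = ncol(window_modes) / 2,
                             width_factor = 4) {
  window_modes <- as.matrix(window_modes)
  L <- ncol(window_modes); n_win <- nrow(window_modes)
  starts <- round((seq_len(n_win) - 1) * hop_samples)
  total <- starts[n_win] + L
  s <- seq_len(L)
  g <- exp(-0.5 * ((s - (L + 1) / 2) / (L / width_factor))^2)
  num <- numeric(total); den <- numeric(total)
  for (l in seq_len(n_win)) {
    idx <- (starts[l] + 1):(starts[l] + L)
    num[idx] <- num[idx] + window_modes[l, ] * g
    den[idx] <- den[idx] + g
  }
  if (any(den <= 0)) stop("coverage gap in window system")
  num / den
}

#' Full-domain reconstruction of the dominant condition modes
#'
#' Re-runs the windowed kurtosis-operator decomposition on a half-overlapping
#' window system (hop = window/2, the reconstruction setup) and overlap-adds
#' each condition's dominant mode with a Gaussian taper, giving one
#' continuous dominant-mode series per condition for multiscale fluctuation
#' analysis.
#'
#' @inheritParams turbulence_field
#' @param width_factor Gaussian taper width factor (default 4).
#' @return Matrix (conditions x samples) with attribute `sampling_rate`.
#' @export
reconstruct_dominant_mode <- function(dataset, window_length, p = 8,
                                      order = 4, width_factor = 4) {
  field <- turbulence_field(dataset, window_length, hop = window_length / 2,
                            p = p, order = order)
  fs <- dataset$sampling_rate
  w <- round(window_length / 1000 * fs)
  times <- (seq_len(w) - 1) / fs
  B <- eval_basis(field$basis, times)
  J <- field$J
  out <- NULL
  for (j in seq_len(J)) {
    wm <- t(vapply(seq_len(field$grid$tau), function(l) {
      blocks <- split_condition_modes(field$modes[l, ], field$p, J)
      drop(B %*% blocks[[j]])
    }, numeric(w)))
    rec <- reconstruct_mode(wm, hop_samples = w / 2,
                            width_factor = width_factor)
    if (is.null(out)) out <- matrix(NA_real_, J, length(rec))
    out[j, ] <- rec
  }
  rownames(out) <- dataset$conditions
  attr(out, "sampling_rate") <- fs
  out
}
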