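test_that("zero-phase band-pass preserves in-band tones and rejects out-of-band ones", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)
  mid <- 1500:2500  # steady state, away from filter edge transients
  y0 <- butterworth_bandpass(rep(0, length(t)), 8, 13, sampling_rate = fs)
  expect_equal(y0, rep(0, length(t)))
  y10 <- butterworth_bandpass(sin(2 * pi * 10 * t), 8, 13, sampling_rate = fs)
  expect_lt(abs(max(abs(y10[mid])) - 1), 0.02)
  y2 <- butterworth_bandpass(sin(2 * pi * 2 * t), 8, 13, sampling_rate = fs)
  expect_lt(20 * log10(max(abs(y2[mid]))), -20)
  expect_error(butterworth_bandpass(y0, 13, 8, sampling_rate = fs), "band edges")
  expect_error(butterworth_bandpass(y0, 8, 600, sampling_rate = fs), "band edges")
  # matrix input filters each channel
  X <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 2 * t))
  Y <- butterworth_bandpass(X, 8, 13, sampling_rate = fs)
  expect_equal(dim(Y), dim(X))
  expect_equal(Y[1, ], y10)
})

test_that("SSD recovers a narrowband source mixed into noisy channels", {
  set.seed(8)
  fs <- 250; M <- fs * 8
  src <- butterworth_bandpass(rnorm(M), 9, 11, sampling_rate = fs)
  src <- src / sd(src)
  mix <- rnorm(8)
  X <- tcrossprod(mix, src) + matrix(rnorm(8 * M, sd = 0.5), 8)
  dec <- ssd_decompose(X, 8, 13, sampling_rate = fs)
  rec <- drop(crossprod(dec$filters[, 1], X))
  expect_gt(abs(cor(rec, src)), 0.95)
  expect_true(all(diff(dec$eigenvalues) <= 1e-9))
  expect_lte(ncol(dec$filters), nrow(X))
  expect_lte(dec$n_selected, ncol(dec$filters))
  den <- ssd_denoise(dec, butterworth_bandpass(X, 8, 13, sampling_rate = fs))
  expect_equal(dim(den), dim(X))
})

test_that("SSD has no preferred direction on white noise", {
  set.seed(9)
  X <- matrix(rnorm(6 * 20000), 6)
  dec <- ssd_decompose(X, 8, 13, sampling_rate = 250)
  # equal in-band and flanking structure: eigenvalue spread stays small
  expect_lt(max(dec$eigenvalues) / min(dec$eigenvalues), 1.6)
})

test_that("perpendicular line method finds the scree elbow", {
  expect_identical(perpendicular_line_select(c(10, 9, 8, 1, 0.9, 0.8)), 3L)
  expect_identical(perpendicular_line_select(seq(10, 1, length.out = 6)), 1L)
  expect_identical(perpendicular_line_select(c(5, 1)), 1L)
  expect_identical(perpendicular_line_select(c(5)), 1L)
  expect_error(perpendicular_line_select(c(1, 2, 3)), "descending")
})

test_that("Cauchy PCA matches truth on rank-1 and Gaussian data", {
  set.seed(6)
  v <- c(3, 1, -2, 0.5, 1); v <- v / sqrt(sum(v^2))
  cp <- cauchy_pca_dominant(tcrossprod(v, rnorm(5000)))
  expect_gt(abs(sum(cp$dominant_direction * v)), 0.99)
  expect_equal(sum(cp$dominant_direction^2), 1, tolerance = 1e-10)
  # canonical sign: largest-magnitude entry positive
  i <- which.max(abs(cp$dominant_direction))
  expect_gt(cp$dominant_direction[i], 0)
  # rank-1 backprojection
  expect_equal(qr(cp$projected)$rank, 1)

  set.seed(7)
  Xg <- t(matrix(rnorm(10000 * 5), 10000, 5) %*% chol(diag(c(4, 1, 1, 1, 1))))
  cpg <- cauchy_pca_dominant(Xg)
  evg <- eigen(cov(t(Xg)), symmetric = TRUE)$vectors[, 1]
  ang <- acos(min(1, abs(sum(cpg$dominant_direction * evg)))) * 180 / pi
  expect_lt(ang, 5)
})

test_that("Cauchy PCA beats Gaussian PCA under amplitude outliers", {
  v <- c(3, 1, -2, 0.5, 1); v <- v / sqrt(sum(v^2))
  ang <- function(u) acos(min(1, abs(sum(u * v))))
  wins <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    X <- tcrossprod(v, rnorm(2000)) + matrix(rnorm(5 * 2000, sd = 0.1), 5)
    idx <- sample(2000, 100)  # 5% of samples replaced by 50x outliers
    X[, idx] <- matrix(rnorm(5 * 100, sd = 5), 5)
    a_c <- ang(cauchy_pca_dominant(X)$dominant_direction)
    a_g <- ang(eigen(cov(t(X)), symmetric = TRUE)$vectors[, 1])
    wins <- wins + (a_c < a_g)
  }
  expect_gte(wins, 18)
})

test_that("band projection returns rank-1 recordings in the requested band", {
  cfg <- small_config(N = 2, J = 1, K = 6, fs = 250, duration = 4, snr = 4)
  ds <- generate_dataset(cfg)
  pr <- band_project(ds, 8, 13, use_ssd = FALSE)
  expect_equal(dim(pr$data), dim(ds$data))
  expect_equal(pr$band, c(8, 13))
  expect_equal(qr(pr$data[1, 1, , ])$rank, 1)
})
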