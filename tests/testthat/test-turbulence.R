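test_that("the turbulence field has the contracted shape and symmetries", {
  cfg <- small_config(N = 3, J = 2, K = 6, fs = 250, duration = 4)
  ds <- generate_dataset(cfg)
  fld <- turbulence_field(ds, window_length = 500, hop = 40, p = 5)
  expect_equal(dim(fld$xi), c(3, 2, fld$grid$tau, 6))
  expect_gte(fld$grid$tau, 2)
  it <- turbulence_intensity(fld)
  expect_true(all(it$intensity >= 0))
  expect_equal(nrow(it), 6)

  # negating the signal leaves every intensity unchanged (sign alignment)
  dsn <- ds; dsn$data <- -dsn$data
  itn <- turbulence_intensity(turbulence_field(dsn, 500, hop = 40, p = 5))
  expect_equal(itn$intensity, it$intensity, tolerance = 1e-10)

  # scaling the signal by c scales every intensity by c^2
  dss <- ds; dss$data <- 3 * ds$data
  its <- turbulence_intensity(turbulence_field(dss, 500, hop = 40, p = 5))
  expect_equal(its$intensity, 9 * it$intensity, tolerance = 1e-8)
})

test_that("turbulence intensity matches its closed forms", {
  expect_equal(turbulence_intensity(matrix(1.5, 10, 4)), 0)
  u <- c(1, 2, 3); v <- c(0, -1, 5)
  alt <- matrix(rbind(u, v)[rep(1:2, 6), ], ncol = 3)
  expect_equal(turbulence_intensity(alt), sum((u - v)^2))
  expect_error(turbulence_intensity(matrix(1, 1, 3)), "tau")
  # K-dimensional random walk: mean squared step norm = K * sigma^2
  set.seed(5)
  K <- 4; sig <- 0.7
  xi <- apply(matrix(rnorm(10000 * K, sd = sig), 10000, K), 2, cumsum)
  expect_lt(abs(turbulence_intensity(xi) - K * sig^2) / (K * sig^2), 0.05)
})

test_that("an abrupt covariance regime switch is localized by the largest adjacent difference", {
  fs <- 200; dur <- 4; M <- fs * dur
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    N <- 10; K <- 6
    half <- M / 2
    e_long <- butterworth_bandpass(rnorm(3 * M), 0.05, 0.2, sampling_rate = fs)
    e <- e_long[(M + 1):(2 * M)]
    e <- 1 + 0.1 * e / sd(e)
    e[(half + 1):M] <- 5 * e[(half + 1):M]      # switch at mid-recording
    amp <- sample(c(-1, 1), N * K, TRUE)
    idx <- sample(N * K, 3)
    amp[idx] <- 8 * sign(amp[idx])              # planted kurtotic direction
    dat <- array(0, dim = c(N, 1, K, M))
    r <- 1
    for (i in 1:N) for (k in 1:K) {
      dat[i, 1, k, ] <- amp[r] * e + rnorm(M, sd = 0.005); r <- r + 1
    }
    d <- as_dataset(dat, fs)
    f <- turbulence_field(d, window_length = 500, hop = 250, p = 4)
    dif <- vapply(seq_len(f$grid$tau - 1), function(l)
      sum((f$xi[, 1, l, ] - f$xi[, 1, l + 1, ])^2), numeric(1))
    # switch at 2000 ms: pairs 7 and 8 touch it; 9 is one window later
    hits <- hits + (which.max(dif) %in% 7:9)
  }
  expect_gte(hits, 7)
})

test_that("dominant eigenvalues are stable across windows under a stationary Gaussian null", {
  set.seed(13)
  p <- 6
  bs <- bspline_basis(p, 4, c(0, 1))
  kap <- replicate(50, {
    A <- matrix(rnorm(64 * p), 64, p)
    wh <- whiten_coefficients(A, bs$gram)
    kurtosis_eigen(kurtosis_matrix(wh$A_white, bs$gram)$Sigma, bs$gram)$values[1]
  })
  expect_lt(sd(kap) / mean(kap), 0.2)
})

test_that("window failures name the window index", {
  cfg <- small_config(N = 1, J = 1, K = 2, fs = 250, duration = 4)
  ds <- generate_dataset(cfg)
  # 2 curves cannot support a p = 5 whitening: every window fails, the first reports
  expect_error(turbulence_field(ds, 500, hop = 40, p = 5), "window 1")
})

test_that("Gaussian overlap-add reconstruction has the stated fixed points", {
  wm <- matrix(1.7, 9, 100)
  r <- reconstruct_mode(wm)
  expect_equal(r, rep(1.7, 500), tolerance = 1e-12)   # partition of unity
  one <- reconstruct_mode(matrix(sin(1:80 / 10), 1, 80))
  expect_equal(one, sin(1:80 / 10))                   # single window
  ramp <- t(vapply(0:8, function(l) (l * 50) + 1:100, numeric(100)))
  expect_true(all(diff(reconstruct_mode(ramp)) >= -1e-9))  # monotone values
})

test_that("full-domain mode reconstruction covers the recording per condition", {
  cfg <- small_config(N = 3, J = 2, K = 4, fs = 250, duration = 4)
  ds <- generate_dataset(cfg)
  rec <- reconstruct_dominant_mode(ds, window_length = 500, p = 5)
  expect_equal(nrow(rec), 2)
  expect_equal(ncol(rec), 1000)
  expect_true(all(is.finite(rec)))
})
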