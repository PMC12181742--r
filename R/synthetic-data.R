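#' Simulation configuration for synthetic multichannel recordings
#'
#' Builds the configuration object consumed by [generate_dataset()] and
#' [generate_behavioral_covariates()]. The defaults mirror a typical
#' motor/emotion EEG study design: 30 participants, 6 task conditions, 64
#' channels, 56-s recordings sampled at 1 kHz, and an alpha-band (8-13 Hz)
#' oscillatory source model. At that scale the full participant x condition x
#' channel x sample array occupies several gigabytes, so analyses of
#' study-scale data are best run per recording; reduced configurations
#' (fewer channels, shorter recordings, lower sampling rate) retain the same
#' statistical structure and are used throughout the package's tests.
#'
#' @param n_participants,n_conditions,n_channels,n_sources Positive counts.
#' @param sampling_rate Sampling rate in Hz.
#' @param duration Recording length in seconds; `duration * sampling_rate`
#'   must be an integer number of samples.
#' @param band_low,band_high Source band edges in Hz (`band_low < band_high <
#'   sampling_rate / 2`).
#' @param source_excess_kurtosis Excess kurtosis of the i.i.d. innovations
#'   driving each source (0 = Gaussian; positive values use a scaled Student-t
#'   with matching fourth moment). Recycled to `n_sources`.
#' @param snr Ratio of band-source power to broadband-noise power per channel;
#'   `Inf` disables the noise floor.
#' @param nonstationarity_level Nonnegative real controlling the rate and
#'   contrast of regime-switching amplitude envelopes; 0 leaves the source
#'   process strictly stationary.
#' @param mixing_seed,noise_seed Integer seeds for the spatial mixing matrix
#'   and for the source/noise innovations, kept separate so the spatial and
#'   temporal structure can be varied independently.
#' @param condition_names Character labels, length `n_conditions`.
#' @param covariate_spec List linking condition index to behavioral
#'   covariates, with elements `ee_location` (latent mean of the 1-5
#'   emotional-engagement scale, per condition), `mvr_meanlog` and `mvr_sdlog`
#'   (log-normal movement-velocity-rate parameters), and `td` (deterministic
#'   task-demand level 1-3 per condition). `NULL` uses defaults in which
#'   engagement rises with expressive/mirroring interaction and velocity with
#'   the movement conditions.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 30, n_conditions = 6,
                              n_channels = 64, sampling_rate = 1000,
                              duration = 56, band_low = 8, band_high = 13,
                              n_sources = 4, source_excess_kurtosis = 0,
                              snr = 1, nonstationarity_level = 0,
                              mixing_seed = 101, noise_seed = 202,
                              condition_names = NULL, covariate_spec = NULL) {
  counts <- c(n_participants, n_conditions, n_channels, n_sources)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all counts must be integers >= 1")
  n_samples <- duration * sampling_rate
  if (abs(n_samples - round(n_samples)) > 1e-8)
    stop("duration * sampling_rate must be an integer number of samples")
  if (!(band_low > 0 && band_low < band_high && band_high < sampling_rate / 2))
    stop("band edges must satisfy 0 < band_low < band_high < sampling_rate/2")
  if (nonstationarity_level < 0) stop("nonstationarity_level must be >= 0")
  if (is.null(condition_names)) {
    base <- c("NM.S.NA", "M.S.NA", "M.NS.Mir", "NM.S.Rob", "NM.S.Exp", "M.S.Mir")
    condition_names <- if (n_conditions <= 6) base[seq_len(n_conditions)] else
      c(base, paste0("cond", 7:n_conditions))
  }
  if (length(condition_names) != n_conditions)
    stop("condition_names must have length n_conditions")
  if (is.null(covariate_spec))
    covariate_spec <- default_covariate_spec(condition_names)
  structure(list(
    n_participants = as.integer(n_participants),
    n_conditions = as.integer(n_conditions),
    n_channels = as.integer(n_channels),
    n_sources = as.integer(n_sources),
    sampling_rate = sampling_rate, duration = duration,
    n_samples = as.integer(round(n_samples)),
    band_low = band_low, band_high = band_high,
    source_excess_kurtosis = rep_len(source_excess_kurtosis, n_sources),
    snr = snr, nonstationarity_level = nonstationarity_level,
    mixing_seed = as.integer(mixing_seed), noise_seed = as.integer(noise_seed),
    condition_names = condition_names, covariate_spec = covariate_spec
  ), class = "simulation_config")
}

default_covariate_spec <- function(condition_names) {
  J <- length(condition_names)
  moving <- grepl("^M\\.", condition_names)
  interactive <- grepl("Mir|Exp", condition_names)
  singing <- grepl("\\.S\\.", condition_names)
  ee <- 2.4 + 0.5 * moving + 0.8 * interactive
  mvr_meanlog <- ifelse(moving, 0, log(0.2))
  td <- pmin(3L, pmax(1L, as.integer(moving + singing + (condition_names != "NM.S.NA" &
                                                           grepl("Mir|Exp|Rob", condition_names)))))
  list(ee_location = ee, mvr_meanlog = mvr_meanlog, mvr_sdlog = 0.4, td = td)
}

# innovations with prescribed excess kurtosis: scaled Student-t (excess 6/(df-4))
source_innovations <- function(n, excess_kurtosis) {
  if (excess_kurtosis <= 0) return(rnorm(n))
  df <- 6 / excess_kurtosis + 4
  rt(n, df = df) * sqrt((df - 2) / df)
}

#' Generate a synthetic participant x condition multichannel dataset
#'
#' Band-limited oscillatory sources (i.i.d. innovations with configurable
#' excess kurtosis, shaped by the band's zero-phase Butterworth filter) are
#' mixed into channels through a fixed random spatial mixing matrix, and
#' broadband Gaussian noise is added at the configured signal-to-noise ratio.
#' If `config$nonstationarity_level > 0`, regime-switching envelopes are
#' applied via [inject_nonstationarity()]. Output is a pure function of the
#' configuration and its seeds.
#'
#' @param config A [simulation_config()].
#' @return An object of class `eeg_dataset`: a list with the numeric array
#'   `data` (participants x conditions x channels x samples), `sampling_rate`,
#'   `channels`, `participants`, `conditions`, `mixing` (the channels x
#'   sources mixing matrix) and `sources` (participants x conditions x sources
#'   x samples array of the noise-free band-limited sources).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  N <- config$n_participants; J <- config$n_conditions
  K <- config$n_channels; M <- config$n_samples; S <- config$n_sources
  mixing <- with_seed(config$mixing_seed, {
    A <- matrix(rnorm(K * S), K, S)
    sweep(A, 2, sqrt(colSums(A^2)), "/")
  })
  dat <- array(0, dim = c(N, J, K, M))
  src <- array(0, dim = c(N, J, S, M))
  for (i in seq_len(N)) for (j in seq_len(J)) {
    rec <- with_seed(config$noise_seed + 7919L * i + 104729L * j, {
      innov <- t(vapply(seq_len(S), function(s)
        source_innovations(M, config$source_excess_kurtosis[s]),
        numeric(M)))
      sources <- butterworth_bandpass(innov, config$band_low, config$band_high,
                                      sampling_rate = config$sampling_rate)
      sources <- sources / pmax(apply(sources, 1, sd), .Machine$double.eps)
      x <- mixing %*% sources
      if (is.finite(config$snr)) {
        p_sig <- mean(apply(x, 1, var))
        x <- x + matrix(rnorm(K * M, sd = sqrt(p_sig / config$snr)), K, M)
      }
      list(x = x, s = sources)
    })
    dat[i, j, , ] <- rec$x
    src[i, j, , ] <- rec$s
  }
  out <- structure(list(
    data = dat, sources = src, mixing = mixing,
    sampling_rate = config$sampling_rate,
    participants = seq_len(N),
    conditions = config$condition_names,
    channels = paste0("ch", seq_len(K)),
    config = config
  ), class = "eeg_dataset")
  if (config$nonstationarity_level > 0)
    out <- inject_nonstationarity(out, config$nonstationarity_level,
                                  seed = config$noise_seed + 1L)
  out
}

#' @export
print.eeg_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_dataset> %d participants x %d conditions x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], d[4], x$sampling_rate))
  invisible(x)
}

#' Inject nonstationary amplitude envelopes into a dataset
#'
#' Multiplies each recording by a piecewise-constant regime-switching
#' envelope shared across channels: regime holding times are exponential with
#' mean `1/level` seconds and regime amplitudes are log-normal multipliers
#' with log-scale `0.5 * level` (unit median), so both the switching rate and
#' the amplitude contrast grow with `level`. `level = 0` returns the input
#' unchanged. The heavy-tailed envelope raises the envelope kurtosis of the
#' signal and, downstream, the turbulence intensity.
#'
#' @param dataset An `eeg_dataset`.
#' @param level Nonnegative nonstationarity level.
#' @param seed Integer seed for the envelope process.
#' @return The dataset with modulated `data` (and `sources`).
#' @export
inject_nonstationarity <- function(dataset, level, seed = 1L) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  if (level < 0) stop("level must be >= 0")
  if (level == 0) return(dataset)
  d <- dim(dataset$data)
  fs <- dataset$sampling_rate
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    env <- with_seed(seed + 7919L * i + 104729L * j,
                     regime_envelope(d[4], fs, level))
    dataset$data[i, j, , ] <- sweep(dataset$data[i, j, , , drop = FALSE],
                                    4, env, "*")
    if (!is.null(dataset$sources))
      dataset$sources[i, j, , ] <- sweep(dataset$sources[i, j, , , drop = FALSE],
                                         4, env, "*")
  }
  dataset
}

regime_envelope <- function(n_samples, fs, level) {
  sdlog <- 0.5 * level
  env <- numeric(0)
  while (length(env) < n_samples) {
    hold <- max(1L, round(rexp(1, rate = level) * fs))
    amp <- rlnorm(1, meanlog = 0, sdlog = sdlog)
    env <- c(env, rep(amp, hold))
  }
  env[seq_len(n_samples)]
}

#' Generate behavioral covariates per participant and condition
#'
#' Emotional engagement (EE, Likert 1-5) is drawn from a condition-dependent
#' categorical distribution (a discretized normal centred on
#' `covariate_spec$ee_location`), the movement velocity rate (MVR) is
#' log-normal with condition-dependent location, and task demand (TD, 1-3) is
#' deterministic per condition.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A `data.frame` with one row per participant x condition and columns
#'   `participant`, `condition`, `EE`, `MVR`, `TD`.
#' @export
generate_behavioral_covariates <- function(config, seed = 303L) {
  stopifnot(inherits(config, "simulation_config"))
  spec <- config$covariate_spec
  J <- config$n_conditions; N <- config$n_participants
  if (length(spec$ee_location) != J || length(spec$mvr_meanlog) != J ||
      length(spec$td) != J)
    stop("covariate_spec entries must have one value per condition")
  if (!all(spec$td %in% 1:3)) stop("task demand must be in 1..3")
  with_seed(seed, {
    rows <- expand.grid(participant = seq_len(N), condition = seq_len(J))
    ee <- integer(nrow(rows)); mvr <- numeric(nrow(rows))
    for (r in seq_len(nrow(rows))) {
      j <- rows$condition[r]
      p <- exp(-0.5 * (1:5 - spec$ee_location[j])^2)
      ee[r] <- sample(1:5, 1, prob = p / sum(p))
      mvr[r] <- rlnorm(1, meanlog = spec$mvr_meanlog[j], sdlog = spec$mvr_sdlog)
    }
    data.frame(participant = rows$participant,
               condition = config$condition_names[rows$condition],
               EE = ee, MVR = mvr, TD = spec$td[rows$condition])
  })
}

#' Write / read the internal recording container
#'
#' Each recording (participant x condition) is stored as a little-endian
#' float64 binary matrix (channels x samples, column-major) next to a single
#' JSON sidecar holding the dimensions, labels and sampling rate.
#'
#' @param dataset An `eeg_dataset`.
#' @param dir Output directory (created if needed).
#' @return `write_eeg_dataset()` returns `dir` invisibly;
#'   `read_eeg_dataset()` returns the reconstructed `eeg_dataset` (without
#'   `sources`/`mixing`, which are simulation-only).
#' @export
write_eeg_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(dataset$data)
  meta <- list(n_participants = d[1], n_conditions = d[2], n_channels = d[3],
               n_samples = d[4], sampling_rate = dataset$sampling_rate,
               participants = dataset$participants,
               conditions = dataset$conditions, channels = dataset$channels)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    con <- file(file.path(dir, sprintf("p%02d_c%02d.bin", i, j)), "wb")
    writeBin(as.numeric(dataset$data[i, j, , ]), con, size = 8,
             endian = "little")
    close(con)
  }
  invisible(dir)
}

#' @rdname write_eeg_dataset
#' @export
read_eeg_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  d <- c(meta$n_participants, meta$n_conditions, meta$n_channels, meta$n_samples)
  dat <- array(0, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    con <- file(file.path(dir, sprintf("p%02d_c%02d.bin", i, j)), "rb")
    dat[i, j, , ] <- readBin(con, "numeric", n = d[3] * d[4], size = 8,
                             endian = "little")
    close(con)
  }
  structure(list(data = dat, sampling_rate = meta$sampling_rate,
                 participants = meta$participants, conditions = meta$conditions,
                 channels = meta$channels), class = "eeg_dataset")
}

#' Write a behavioral covariate table as CSV
#'
#' @param table Data frame with columns `participant,condition,EE,MVR,TD`.
#' @param path Output file path.
#' @export
write_behavioral_csv <- function(table, path) {
  stopifnot(all(c("participant", "condition", "EE", "MVR", "TD") %in% names(table)))
  write.csv(table[, c("participant", "condition", "EE", "MVR", "TD")], path,
            row.names = FALSE)
  invisible(path)
}
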