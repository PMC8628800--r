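#' Stage-conditioned synthesis parameters
#'
#' Parameters of the synthetic EEG/EMG generator. Each stage gets relative
#' amplitudes for a delta (1-4 Hz) comb, a theta (6-9 Hz) comb and a broadband
#' (11-19 Hz) comb of sinusoids, plus an EMG amplitude scale in microvolt RMS.
#' Defaults encode the murine stage signatures the classifier relies on:
#' NREM has dominant delta power and low muscle tone, REM has dominant theta
#' power with atonia, wake has mixed low-amplitude EEG and high EMG.
#'
#' @param band_weights Named list (`WAKE`, `NREM`, `REM`), each a numeric
#'   vector `c(delta=, theta=, broadband=)` of relative amplitudes (unitless,
#'   scaled by `eeg_amp_uV`).
#' @param emg_uV Named numeric vector of per-stage EMG RMS amplitudes in
#'   microvolts. Must satisfy `WAKE > NREM >= REM` (atonia ordering).
#' @param eeg_amp_uV Base EEG component amplitude in microvolts.
#' @param noise_uV Amplitude scale of the 1/f background noise in microvolts.
#' @param fs Sampling rate in Hz; must be at least twice the highest
#'   synthesized frequency.
#' @param freq_jitter_hz Half-width of the uniform per-epoch frequency jitter
#'   applied to every comb component.
#' @param band_freqs Named list of comb frequencies (Hz) per band; override
#'   for controlled experiments (e.g. a single pure tone).
#' @return A validated list of class `stage_params`.
#' @export
stage_params <- function(
    band_weights = list(
      WAKE = c(delta = 0.5, theta = 0.8, broadband = 1.0),
      NREM = c(delta = 2.5, theta = 0.8, broadband = 0.5),
      REM  = c(delta = 0.6, theta = 2.2, broadband = 0.5)
    ),
    emg_uV = c(WAKE = 30, NREM = 8, REM = 4),
    eeg_amp_uV = 20,
    noise_uV = 6,
    fs = 128,
    freq_jitter_hz = 0.15,
    band_freqs = list(
      delta = c(1, 2, 3, 4),
      theta = c(6, 7, 8, 9),
      broadband = c(11, 13, 15, 17, 19)
    )) {
  p <- list(band_weights = band_weights, emg_uV = emg_uV,
            eeg_amp_uV = eeg_amp_uV, noise_uV = noise_uV, fs = fs,
            freq_jitter_hz = freq_jitter_hz, band_freqs = band_freqs)
  class(p) <- "stage_params"
  validate_stage_params(p)
  p
}

validate_stage_params <- function(p) {
  for (s in SLEEP_STAGES) {
    w <- p$band_weights[[s]]
    if (is.null(w) || any(!is.finite(w)) || any(w < 0)) {
      stop("band_weights for stage ", s, " must be finite and non-negative")
    }
  }
  if (any(p$emg_uV < 0) || p$eeg_amp_uV < 0 || p$noise_uV < 0) {
    stop("amplitudes must be non-negative")
  }
  max_f <- max(unlist(p$band_freqs)) + p$freq_jitter_hz
  if (p$fs < 2 * max_f) {
    stop("sampling rate ", p$fs, " Hz violates Nyquist for the ",
         max_f, " Hz band")
  }
  bw <- p$band_weights
  if (!(bw$NREM["delta"] > bw$NREM["theta"])) {
    stop("NREM delta weight must exceed NREM theta weight")
  }
  if (!(bw$REM["theta"] > bw$REM["delta"])) {
    stop("REM theta weight must exceed REM delta weight")
  }
  e <- p$emg_uV
  if (!(e["WAKE"] > e["NREM"] && e["NREM"] >= e["REM"])) {
    stop("EMG scales must satisfy WAKE > NREM >= REM")
  }
  invisible(p)
}

#' Stage-transition configuration
#'
#' First-order Markov model over (WAKE, NREM, REM). The default matrix was
#' chosen so that its stationary distribution is exactly 10:10:1
#' (wake:NREM:REM), the epoch ratio of a conventionally housed mouse, with a
#' mean REM bout of 2.5 epochs and REM reachable only from NREM.
#'
#' @param matrix 3x3 row-stochastic transition matrix, rows and columns
#'   ordered (WAKE, NREM, REM).
#' @param initial Initial stage distribution; defaults to the stationary
#'   distribution of `matrix`.
#' @return A validated list of class `transition_config`.
#' @export
transition_config <- function(
    matrix = rbind(
      WAKE = c(0.950, 0.050, 0.00),
      NREM = c(0.015, 0.945, 0.04),
      REM  = c(0.350, 0.050, 0.60)
    ),
    initial = NULL) {
  matrix <- as.matrix(matrix)
  dimnames(matrix) <- list(SLEEP_STAGES, SLEEP_STAGES)
  if (any(matrix < 0)) {
    bad <- which(apply(matrix, 1, function(r) any(r < 0)))[1]
    stop("transition matrix row ", SLEEP_STAGES[bad], " has negative entries")
  }
  rs <- rowSums(matrix)
  off <- which(abs(rs - 1) > 1e-9)
  if (length(off) > 0) {
    stop("transition matrix row ", SLEEP_STAGES[off[1]],
         " sums to ", format(rs[off[1]], digits = 12), ", not 1")
  }
  if (matrix["WAKE", "REM"] != 0) {
    stop("P(WAKE -> REM) must be 0: REM is entered only from NREM")
  }
  if (is.null(initial)) initial <- stationary_distribution(matrix)
  initial <- initial / sum(initial)
  cfg <- list(matrix = matrix, initial = stats::setNames(initial, SLEEP_STAGES))
  class(cfg) <- "transition_config"
  cfg
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized to
#' sum to one.
#'
#' @param matrix Row-stochastic square matrix.
#' @return Numeric vector summing to 1.
#' @export
stationary_distribution <- function(matrix) {
  e <- eigen(t(matrix))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Simulate a hypnogram from the Markov stage model
#'
#' Draws the first stage from the configured initial distribution and each
#' subsequent stage from the transition row of its predecessor. Fully
#' reproducible from `seed`.
#'
#' @param n_epochs Number of epochs (>= 0).
#' @param config A [transition_config()].
#' @param seed Integer seed.
#' @param epoch_length_s Epoch length in seconds.
#' @return A [hypnogram()] of length `n_epochs`.
#' @examples
#' h <- simulate_hypnogram(500, seed = 1)
#' stage_counts(h)
#' @export
simulate_hypnogram <- function(n_epochs, config = transition_config(),
                               seed = 1, epoch_length_s = 20) {
  stopifnot(inherits(config, "transition_config"), n_epochs >= 0)
  if (n_epochs == 0) return(hypnogram(character(0), epoch_length_s))
  stages <- integer(n_epochs)
  cum_init <- cumsum(config$initial)
  cum_rows <- t(apply(config$matrix, 1, cumsum))
  local_seed(seed)
  u <- runif(n_epochs)
  stages[1] <- findInterval(u[1], cum_init, left.open = TRUE) + 1L
  for (i in seq_len(n_epochs - 1L)) {
    stages[i + 1L] <-
      findInterval(u[i + 1L], cum_rows[stages[i], ], left.open = TRUE) + 1L
  }
  hypnogram(SLEEP_STAGES[stages], epoch_length_s)
}

#' Synthesize stage-conditioned EEG/EMG signals for a hypnogram
#'
#' Per epoch, the EEG is a sum of three sinusoid combs (delta, theta,
#' broadband) with per-epoch random phases and a small uniform frequency
#' jitter, weighted by the epoch stage's band amplitudes, plus 1/f background
#' noise; the EMG is zero-mean Gaussian noise scaled to the stage's RMS
#' amplitude. One user seed governs the record through a counter-based
#' sub-seed per epoch, so any contiguous slice is reproducible.
#'
#' @param hypnogram A non-empty [hypnogram()].
#' @param params A [stage_params()].
#' @param seed Integer seed.
#' @return A `signal_record` list: `eeg`, `emg` (microvolt sample vectors),
#'   `fs`, `epoch_length_s`, `n_epochs`.
#' @examples
#' h <- simulate_hypnogram(3, seed = 1)
#' rec <- synthesize_signals(h, seed = 1)
#' length(rec$eeg) # 3 * 20 * 128
#' @export
synthesize_signals <- function(hypnogram, params = stage_params(), seed = 1) {
  validate_stage_params(params)
  stages <- stage_sequence(hypnogram)
  if (length(stages) == 0) stop("hypnogram must be non-empty")
  el <- epoch_length(hypnogram)
  fs <- params$fs
  spe <- el * fs
  if (abs(spe - round(spe)) > 1e-9) {
    stop("epoch length (", el, " s) x sampling rate (", fs,
         " Hz) must be an integer number of samples")
  }
  spe <- as.integer(round(spe))
  tt <- (seq_len(spe) - 1) / fs
  n <- length(stages)
  eeg <- numeric(n * spe)
  emg <- numeric(n * spe)
  for (i in seq_len(n)) {
    local_seed(derive_seed(seed, i))
    st <- stages[i]
    w <- params$band_weights[[st]]
    x <- numeric(spe)
    for (b in names(params$band_freqs)) {
      f0 <- params$band_freqs[[b]]
      k <- length(f0)
      f <- f0 + runif(k, -params$freq_jitter_hz, params$freq_jitter_hz)
      ph <- runif(k, 0, 2 * pi)
      amp <- params$eeg_amp_uV * w[[b]] / sqrt(k)
      for (j in seq_len(k)) {
        x <- x + amp * sin(2 * pi * f[j] * tt + ph[j])
      }
    }
    x <- x + params$noise_uV * pink_noise(spe)
    idx <- ((i - 1L) * spe + 1L):(i * spe)
    eeg[idx] <- x
    emg[idx] <- rnorm(spe) * params$emg_uV[[st]]
  }
  structure(
    list(eeg = eeg, emg = emg, fs = fs, epoch_length_s = el, n_epochs = n),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record: %d epochs x %gs @ %g Hz (%d samples)>\n",
              x$n_epochs, x$epoch_length_s, x$fs, length(x$eeg)))
  invisible(x)
}

# 1/f ("pink") noise by spectral shaping of white noise; unit variance.
pink_noise <- function(n) {
  w <- rnorm(n)
  spec <- fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # fold to two-sided frequency index
  spec <- spec / sqrt(f)
  x <- Re(fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Deterministic counter-based sub-seed, kept inside 32-bit integer range.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 16807) %%
               2147483647)
}

# set.seed without clobbering the caller's RNG state on exit
local_seed <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  invisible(old)
}

#' Read / write signal records as CSV plus a JSON sidecar
#'
#' The CSV has columns `eeg_uV`, `emg_uV`; the sidecar (same path with
#' `.json` appended) records `fs`, `epoch_length_s` and `n_epochs`.
#'
#' @param record A `signal_record`.
#' @param path CSV path.
#' @return `write_signal_record()` returns `path` invisibly;
#'   `read_signal_record()` returns a `signal_record`.
#' @export
write_signal_record <- function(record, path) {
  utils::write.csv(
    data.frame(eeg_uV = record$eeg, emg_uV = record$emg),
    path, row.names = FALSE
  )
  jsonlite::write_json(
    list(fs = record$fs, epoch_length_s = record$epoch_length_s,
         n_epochs = record$n_epochs),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_signal_record
#' @export
read_signal_record <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(eeg = df$eeg_uV, emg = df$emg_uV, fs = as.numeric(meta$fs),
         epoch_length_s = as.numeric(meta$epoch_length_s),
         n_epochs = as.integer(meta$n_epochs)),
    class = "signal_record"
  )
}
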