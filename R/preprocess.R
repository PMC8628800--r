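#' Slice a signal record into epochs
#'
#' Splits the paired EEG/EMG arrays into contiguous, non-overlapping epochs of
#' `epoch_length_s` seconds in temporal order.
#'
#' @param record A `signal_record` (see [synthesize_signals()] /
#'   [read_signal_record()]).
#' @return A list with one element per epoch, each a list `eeg`, `emg` of
#'   `fs * epoch_length_s` samples.
#' @export
epoch_slices <- function(record) {
  stopifnot(length(record$eeg) == length(record$emg), record$fs > 0)
  if (any(!is.finite(record$eeg)) || any(!is.finite(record$emg))) {
    stop("signal contains non-finite samples")
  }
  spe <- record$fs * record$epoch_length_s
  if (abs(spe - round(spe)) > 1e-9) {
    stop("fs x epoch_length_s must be an integer sample count")
  }
  spe <- as.integer(round(spe))
  n_total <- length(record$eeg)
  if (n_total %% spe != 0) {
    stop("signal length ", n_total, " is not a multiple of ", spe,
         " samples (one ", record$epoch_length_s, " s epoch at ",
         record$fs, " Hz)")
  }
  n <- n_total %/% spe
  lapply(seq_len(n), function(i) {
    idx <- ((i - 1L) * spe + 1L):(i * spe)
    list(eeg = record$eeg[idx], emg = record$emg[idx])
  })
}

#' Power spectrum of an EEG window in 1-s bins
#'
#' For each non-overlapping 1-second segment of the window, computes the
#' squared DFT magnitude (rectangular window) at the integer frequencies
#' 1..20 Hz. Columns are time-ordered 1-s bins; rows are frequencies, 1 Hz at
#' row 1.
#'
#' @param eeg_window Numeric sample vector; length must be a whole number of
#'   seconds at `fs`.
#' @param fs Sampling rate in Hz; must be >= 40 (Nyquist for the 20 Hz band).
#' @return 20 x n_seconds numeric matrix of raw power.
#' @examples
#' x <- sin(2 * pi * 5 * (0:2559) / 128)  # pure 5 Hz tone, 20 s at 128 Hz
#' p <- compute_power_spectrum(x, fs = 128)
#' which.max(p[, 1]) # 5
#' @export
compute_power_spectrum <- function(eeg_window, fs) {
  if (fs < 40) {
    stop("fs must be >= 40 Hz so the 1-20 Hz band is below Nyquist")
  }
  fs <- as.integer(round(fs))
  n <- length(eeg_window)
  if (n == 0 || n %% fs != 0) {
    stop("window length ", n, " is not a whole number of seconds at fs = ", fs)
  }
  segs <- matrix(eeg_window, nrow = fs)       # one 1-s bin per column
  spec <- stats::mvfft(segs)
  # DFT bin k (0-based) of a 1-s window at fs Hz is exactly k Hz
  pow <- Mod(spec[2:21, , drop = FALSE])^2
  rownames(pow) <- paste0(1:20, "Hz")
  pow
}

#' Normalize a spectrogram to the unit interval
#'
#' Min-max scaling over the whole matrix (each heatmap's brightness is scaled
#' independently of every other epoch). A constant matrix maps to all zeros.
#' Optionally log-compresses power (`log1p`) before scaling.
#'
#' @param raw Non-negative power matrix from [compute_power_spectrum()].
#' @param log_power Apply `log1p` before scaling (default `FALSE`).
#' @return Matrix of the same shape with values in \[0, 1\] and attribute
#'   `normalized = TRUE`.
#' @export
normalize_spectrogram <- function(raw, log_power = FALSE) {
  if (any(raw < 0)) {
    stop("internal consistency error: negative spectral power")
  }
  x <- if (log_power) log1p(raw) else raw
  rng <- range(x)
  out <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
  attr(out, "normalized") <- TRUE
  out
}

#' Per-epoch band power summary
#'
#' Convenience tidier: delta (1-4 Hz) and theta (6-9 Hz) EEG band power and
#' EMG RMS per epoch. Useful for diagnostics and simple baselines.
#'
#' @param record A `signal_record`.
#' @return Tibble with columns `epoch`, `delta_power`, `theta_power`,
#'   `emg_rms`.
#' @export
epoch_band_summary <- function(record) {
  slices <- epoch_slices(record)
  purrr::map_dfr(seq_along(slices), function(i) {
    p <- compute_power_spectrum(slices[[i]]$eeg, record$fs)
    tibble::tibble(
      epoch = i,
      delta_power = mean(p[1:4, ]),
      theta_power = mean(p[6:9, ]),
      emg_rms = sqrt(mean(slices[[i]]$emg^2))
    )
  })
}
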