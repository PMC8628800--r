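#' Minimal EDF (European Data Format) reader
#'
#' Reads continuous EDF recordings: the fixed-width ASCII header plus 16-bit
#' little-endian sample records, applying each channel's physical calibration
#' (physical min/max against digital min/max). Supports channel selection by
#' label or index. Covers plain EDF with equal record counts per channel; no
#' EDF+ annotations.
#'
#' @param path EDF file path.
#' @param eeg_channel,emg_channel Channel label (exact match) or 1-based index.
#' @param epoch_length_s Epoch length to attach to the returned record.
#' @return A `signal_record` with `eeg`, `emg`, `fs`, `epoch_length_s`,
#'   `n_epochs` (epochs are counted as complete windows; a trailing partial
#'   epoch is dropped from `n_epochs` but kept in the arrays).
#' @export
read_edf <- function(path, eeg_channel = 1, emg_channel = 2,
                     epoch_length_s = 20) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- hdr(8)
  if (version != "0") stop("not an EDF file (version field = ", version, ")")
  hdr(80); hdr(80); hdr(8); hdr(8)        # patient, recording, date, time
  n_header <- as.integer(hdr(8))
  hdr(44)                                  # reserved
  n_records <- as.integer(hdr(8))
  record_s <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  field <- function(w) vapply(seq_len(ns), function(i) hdr(w), character(1))
  labels <- field(16)
  field(80); field(8)                      # transducer, dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)                                # prefiltering
  nsamp <- as.integer(field(8))
  field(32)                                # reserved per channel
  seek(con, n_header)

  pick <- function(ch) {
    if (is.character(ch)) {
      i <- match(ch, labels)
      if (is.na(i)) {
        stop("channel '", ch, "' not found; available: ",
             paste(labels, collapse = ", "))
      }
      i
    } else {
      if (ch < 1 || ch > ns) stop("channel index ", ch, " out of 1..", ns)
      as.integer(ch)
    }
  }
  i_eeg <- pick(eeg_channel)
  i_emg <- pick(emg_channel)
  if (nsamp[i_eeg] != nsamp[i_emg]) {
    stop("EEG and EMG channels have different sampling rates")
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offs <- phys_min - gain * dig_min
  per_rec <- sum(nsamp)
  eeg <- vector("list", n_records)
  emg <- vector("list", n_records)
  starts <- cumsum(c(0, nsamp))
  for (r in seq_len(n_records)) {
    d <- readBin(con, "integer", per_rec, size = 2, endian = "little",
                 signed = TRUE)
    if (length(d) < per_rec) stop("truncated EDF data record ", r)
    eeg[[r]] <- d[(starts[i_eeg] + 1):(starts[i_eeg] + nsamp[i_eeg])] *
      gain[i_eeg] + offs[i_eeg]
    emg[[r]] <- d[(starts[i_emg] + 1):(starts[i_emg] + nsamp[i_emg])] *
      gain[i_emg] + offs[i_emg]
  }
  fs <- nsamp[i_eeg] / record_s
  eeg <- unlist(eeg)
  structure(
    list(eeg = eeg, emg = unlist(emg), fs = fs,
         epoch_length_s = epoch_length_s,
         n_epochs = floor(length(eeg) / (fs * epoch_length_s))),
    class = "signal_record"
  )
}

#' Write a signal record as a two-channel EDF file
#'
#' Companion writer for [read_edf()]; samples are quantized to the 16-bit
#' digital range against symmetric physical limits.
#'
#' @param record A `signal_record`; `fs * record_s` must be an integer.
#' @param path Output path.
#' @param record_s EDF data-record duration in seconds.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path, record_s = 1) {
  fs <- record$fs
  nsamp <- fs * record_s
  if (abs(nsamp - round(nsamp)) > 1e-9) stop("fs * record_s must be integer")
  nsamp <- as.integer(round(nsamp))
  n_records <- length(record$eeg) %/% nsamp
  if (n_records * nsamp != length(record$eeg)) {
    stop("signal length must be a whole number of EDF records")
  }
  chans <- list(eeg = record$eeg, emg = record$emg)
  labels <- c("EEG", "EMG")
  # round the physical range up to the 2 decimals the header stores, so the
  # reader's calibration matches the writer's quantization exactly
  pmaxs <- ceiling(vapply(chans, function(x) max(abs(x), 1e-2), numeric(1)) *
                     100) / 100
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    s <- formatC(as.character(x), width = -w)
    writeChar(substr(s, 1, w), con, nchars = w, eos = NULL)
  }
  ns <- 2L
  n_header <- 256L + 256L * ns
  pad("0", 8); pad("synthetic", 80); pad("synthetic", 80)
  pad("01.01.26", 8); pad("00.00.00", 8)
  pad(n_header, 8); pad("", 44); pad(n_records, 8); pad(record_s, 8); pad(ns, 4)
  for (l in labels) pad(l, 16)
  for (i in 1:ns) pad("", 80)
  for (i in 1:ns) pad("uV", 8)
  for (i in 1:ns) pad(formatC(-pmaxs[i], format = "f", digits = 2), 8)
  for (i in 1:ns) pad(formatC(pmaxs[i], format = "f", digits = 2), 8)
  for (i in 1:ns) pad(-32768L, 8)
  for (i in 1:ns) pad(32767L, 8)
  for (i in 1:ns) pad("", 80)
  for (i in 1:ns) pad(nsamp, 8)
  for (i in 1:ns) pad("", 32)
  dig <- lapply(seq_along(chans), function(i) {
    as.integer(round((chans[[i]] + pmaxs[i]) / (2 * pmaxs[i]) * 65535 - 32768))
  })
  for (r in seq_len(n_records)) {
    idx <- ((r - 1L) * nsamp + 1L):(r * nsamp)
    for (i in 1:ns) {
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
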