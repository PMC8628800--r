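# Independent oracles and small shared fixtures.
# Every oracle here is coded from the definition, independently of the
# package's own implementation path.

# Direct DFT band power at integer frequencies 1..20 Hz, per 1-s bin,
# rectangular window. Literal O(n^2) sum, no FFT.
oracle_power_spectrum <- function(x, fs) {
  n_bins <- length(x) / fs
  stopifnot(n_bins == round(n_bins))
  out <- matrix(0, 20, n_bins)
  tt <- 0:(fs - 1)
  for (b in seq_len(n_bins)) {
    seg <- x[((b - 1) * fs + 1):(b * fs)]
    for (k in 1:20) {
      re <- sum(seg * cos(2 * pi * k * tt / fs))
      im <- -sum(seg * sin(2 * pi * k * tt / fs))
      out[k, b] <- re^2 + im^2
    }
  }
  out
}

# Full-spectrum power of one 1-s bin (all DFT bins), for Parseval checks.
oracle_full_power <- function(seg) {
  fs <- length(seg)
  tt <- 0:(fs - 1)
  vapply(0:(fs - 1), function(k) {
    re <- sum(seg * cos(2 * pi * k * tt / fs))
    im <- -sum(seg * sin(2 * pi * k * tt / fs))
    re^2 + im^2
  }, numeric(1))
}

# Brute-force specification of the REM-in-wake smoothing rule: enumerate
# maximal REM runs, test flanks and length, relabel.
oracle_rem_filter <- function(stages, max_bout) {
  n <- length(stages)
  out <- stages
  i <- 1
  while (i <= n) {
    if (stages[i] == "REM") {
      j <- i
      while (j < n && stages[j + 1] == "REM") j <- j + 1
      run_len <- j - i + 1
      has_flanks <- i > 1 && j < n
      if (run_len <= max_bout && has_flanks &&
          stages[i - 1] == "WAKE" && stages[j + 1] == "WAKE") {
        out[i:j] <- "WAKE"
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# Two-feature threshold classifier (EMG RMS + delta/theta ratio), fitted by
# grid search on training epochs. Establishes that the synthetic fixture is
# separable, so classifier tests are meaningful.
fit_two_feature_classifier <- function(feat_train, labels_train) {
  rms_grid <- stats::quantile(feat_train$emg_rms, seq(0.05, 0.95, 0.05))
  ratio <- feat_train$theta_power / pmax(feat_train$delta_power, 1e-12)
  ratio_grid <- stats::quantile(ratio, seq(0.05, 0.95, 0.05))
  best <- list(acc = -1)
  for (t1 in rms_grid) {
    for (t2 in ratio_grid) {
      pred <- ifelse(feat_train$emg_rms > t1, "WAKE",
                     ifelse(ratio > t2, "REM", "NREM"))
      acc <- mean(pred == labels_train)
      if (acc > best$acc) best <- list(acc = acc, t1 = t1, t2 = t2)
    }
  }
  best
}

predict_two_feature <- function(fit, feat) {
  ratio <- feat$theta_power / pmax(feat$delta_power, 1e-12)
  ifelse(feat$emg_rms > fit$t1, "WAKE", ifelse(ratio > fit$t2, "REM", "NREM"))
}

# Small labeled image set at 32 px for fast classifier tests; cached per
# session.
tiny_image_set <- local({
  cache <- new.env()
  function(n_epochs = 60, seed = 11, subject_id = "t1", out_px = 32) {
    key <- paste(n_epochs, seed, subject_id, out_px, sep = "_")
    if (is.null(cache[[key]])) {
      h <- simulate_hypnogram(n_epochs, seed = seed)
      rec <- synthesize_signals(h, seed = seed)
      cache[[key]] <- build_window_images(rec, h, out_px = out_px,
                                          subject_id = subject_id)
    }
    cache[[key]]
  }
})

# Desk-scale classifier profile used across classifier tests; any field can
# be overridden through `...`.
tiny_classifier_config <- function(..., seed = 1) {
  args <- utils::modifyList(
    list(input_px = 32, filters_per_block = c(4, 8, 16, 16, 16),
         learning_rate = 1e-3, batch_size = 16, max_epochs = 8,
         patience = 8, seed = seed),
    list(...)
  )
  do.call(classifier_config, args)
}

# All length-n stage sequences (3^n rows), for exhaustive filter checks.
all_hypnograms <- function(n) {
  m <- as.matrix(expand.grid(rep(list(SLEEP_STAGES), n),
                             stringsAsFactors = FALSE))
  dimnames(m) <- NULL
  m
}
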