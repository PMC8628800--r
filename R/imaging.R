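#' Render one epoch window as a grayscale image
#'
#' Pure rasterization, no plotting toolkit: the top half of the square image
#' is the EMG trace drawn as a column-wise min/max waveform against a fixed
#' vertical range (values clipped to +/- `emg_range`), the bottom half is the
#' normalized power-spectrum heatmap with brightness equal to normalized
#' power and the lowest frequency at the bottom. Identical inputs give
#' bit-identical pixels on any platform.
#'
#' @param emg_window Numeric EMG sample vector (non-empty).
#' @param spectrogram Normalized spectrogram matrix from
#'   [normalize_spectrogram()] (frequencies in rows, 1-s bins in columns).
#' @param emg_range Positive half-range of the fixed EMG axis in microvolts.
#' @param out_px Image side length in pixels (>= 32); 800 is the native
#'   rendering size, 180 the default training size.
#' @return `out_px` x `out_px` numeric matrix in \[0, 1\] (row 1 = top).
#' @export
render_epoch_image <- function(emg_window, spectrogram, emg_range,
                               out_px = 180) {
  if (length(emg_window) == 0) stop("EMG window is empty")
  stopifnot(emg_range > 0, out_px >= 32)
  if (!isTRUE(attr(spectrogram, "normalized")) &&
      (min(spectrogram) < 0 || max(spectrogram) > 1)) {
    stop("spectrogram must be normalized to [0, 1]")
  }
  half <- out_px %/% 2L
  img <- matrix(0, nrow = out_px, ncol = out_px)

  # Both panels rasterize a resolution-independent continuous field by exact
  # box-area coverage, so rendering at a high resolution and area-averaging
  # down agrees with rendering directly at the low resolution.

  # --- top panel: EMG waveform envelope, fixed vertical axis ---
  v <- pmin(pmax(emg_window / emg_range, -1), 1)
  y <- (1 - v) / 2                                # +range -> 0 (panel top)
  n <- length(y)
  y_next <- c(y[-1], y[n])
  lo <- pmin(y, y_next)
  hi <- pmax(y, y_next)
  thin <- (hi - lo) < TRACE_STROKE
  mid <- (lo + hi) / 2
  lo[thin] <- pmin(pmax(mid[thin] - TRACE_STROKE / 2, 0), 1 - TRACE_STROKE)
  hi[thin] <- lo[thin] + TRACE_STROKE
  img[seq_len(half), ] <- render_trace(lo, hi, half, out_px)

  # --- bottom panel: spectrogram heatmap, low frequency at the bottom ---
  sflip <- spectrogram[rev(seq_len(nrow(spectrogram))), , drop = FALSE]
  bh <- out_px - half
  img[(half + 1L):out_px, ] <-
    area_overlap(bh, nrow(sflip)) %*% sflip %*% t(area_overlap(out_px,
                                                               ncol(sflip)))
  img
}

# Minimum stroke thickness of the EMG trace, as a fraction of panel height.
TRACE_STROKE <- 0.01

# Row-overlap matrix for exact box-filter resampling between grids of
# n_in and n_out cells over the same interval; rows sum to 1.
area_overlap <- function(n_out, n_in) {
  step <- n_in / n_out
  m <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    a <- (i - 1) * step
    b <- i * step
    for (j in (floor(a) + 1L):min(ceiling(b), n_in)) {
      m[i, j] <- min(b, j) - max(a, j - 1)
    }
  }
  m / step
}

#' Area-average image downscaling
#'
#' Exact box-filter resampling for arbitrary integer sizes: each output pixel
#' is the average of the input region it covers, with fractional edge
#' overlap.
#'
#' @param img Numeric matrix.
#' @param out_h,out_w Output dimensions (`out_w` defaults to `out_h`).
#' @return `out_h` x `out_w` matrix.
#' @export
downscale_image <- function(img, out_h, out_w = out_h) {
  area_overlap(out_h, nrow(img)) %*% img %*% t(area_overlap(out_w,
                                                            ncol(img)))
}

#' Build labeled window images for a whole record
#'
#' Renders one image per scoring epoch. In 1-epoch mode each image spans its
#' own epoch; in 2-epoch mode each image spans the previous plus the current
#' epoch and is labeled by the latter (current) epoch, so the first epoch of
#' the record yields no image. `window_s_override` trims each window to its
#' most recent seconds before rendering (the shortened-window ladder
#' 40, 35, 30, 25, 20 s).
#'
#' @param record A `signal_record`.
#' @param labels A [hypnogram()] with one label per epoch of `record`.
#' @param epochs_per_image 1 or 2.
#' @param window_s_override Optional window length in seconds, at most
#'   `epochs_per_image * epoch_length_s`.
#' @param out_px Image side length.
#' @param emg_range EMG axis half-range; defaults to 6x the record's global
#'   EMG standard deviation (a fixed axis across all images of the record).
#'   Pass a shared value when imaging several subjects together.
#' @param subject_id Subject tag attached to every image.
#' @param log_power Passed to [normalize_spectrogram()].
#' @return An `image_dataset` tibble: columns `image` (list of matrices),
#'   `label`, `subject_id`, `epoch_index`, `window_s`, `provenance`.
#' @export
build_window_images <- function(record, labels, epochs_per_image = 1,
                                window_s_override = NULL, out_px = 180,
                                emg_range = NULL, subject_id = "s1",
                                log_power = FALSE) {
  stopifnot(epochs_per_image %in% c(1L, 2L))
  slices <- epoch_slices(record)
  stage <- stage_sequence(labels)
  if (length(stage) != length(slices)) {
    stop("label count (", length(stage), ") != epoch count (",
         length(slices), ")")
  }
  if (is.null(emg_range)) emg_range <- 6 * stats::sd(record$emg)
  el <- record$epoch_length_s
  full_s <- epochs_per_image * el
  win_s <- if (is.null(window_s_override)) full_s else window_s_override
  if (win_s <= 0 || win_s > full_s) {
    stop("window_s_override must be in (0, ", full_s, "]")
  }
  if (abs(win_s - round(win_s)) > 1e-9) {
    stop("window_s_override must be a whole number of seconds")
  }
  win_samp <- as.integer(round(win_s * record$fs))
  first <- if (epochs_per_image == 2L) 2L else 1L
  idx <- seq(first, length(slices))
  imgs <- purrr::map(idx, function(i) {
    eeg <- if (epochs_per_image == 2L) {
      c(slices[[i - 1L]]$eeg, slices[[i]]$eeg)
    } else {
      slices[[i]]$eeg
    }
    emg <- if (epochs_per_image == 2L) {
      c(slices[[i - 1L]]$emg, slices[[i]]$emg)
    } else {
      slices[[i]]$emg
    }
    keep <- (length(eeg) - win_samp + 1L):length(eeg)   # most recent win_s
    sg <- normalize_spectrogram(
      compute_power_spectrum(eeg[keep], record$fs), log_power = log_power
    )
    render_epoch_image(emg[keep], sg, emg_range, out_px)
  })
  image_dataset(tibble::tibble(
    image = imgs,
    label = stage[idx],
    subject_id = subject_id,
    epoch_index = idx,
    window_s = win_s,
    provenance = "real"
  ))
}

#' Plot an epoch image
#'
#' @param img Image matrix from [render_epoch_image()] (or one element of an
#'   `image_dataset`'s `image` column).
#' @return A ggplot raster of the image.
#' @export
plot_epoch_image <- function(img) {
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$value <- img[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}
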