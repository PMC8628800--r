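#' Sleep-stage alphabet
#'
#' The three-stage vocabulary used throughout the package, in canonical order.
#' Ties in classifier argmax are broken toward the earlier stage in this order.
#'
#' @format Character vector `c("WAKE", "NREM", "REM")`.
#' @export
SLEEP_STAGES <- c("WAKE", "NREM", "REM")

#' Construct a hypnogram
#'
#' A hypnogram is the per-epoch sequence of sleep-stage labels over a
#' recording. It is represented as a tibble with one row per epoch
#' (columns `epoch` and `stage`) and carries the epoch length in seconds as
#' an attribute, so it pipes through dplyr verbs like any data frame.
#'
#' @param stages Character vector (or factor) of stage labels drawn from
#'   [SLEEP_STAGES].
#' @param epoch_length_s Epoch length in seconds (default 20, the standard
#'   scoring window for mice).
#' @return A tibble of class `hypnogram` with columns `epoch` (1-based index)
#'   and `stage` (factor with levels `WAKE`, `NREM`, `REM`).
#' @examples
#' h <- hypnogram(c("WAKE", "WAKE", "NREM", "REM"))
#' stage_counts(h)
#' @export
hypnogram <- function(stages, epoch_length_s = 20) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), SLEEP_STAGES)
  if (length(bad) > 0) {
    stop("Unknown stage label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(SLEEP_STAGES, collapse = ", "))
  }
  if (!is.numeric(epoch_length_s) || length(epoch_length_s) != 1 ||
      epoch_length_s <= 0) {
    stop("`epoch_length_s` must be a single positive number")
  }
  out <- tibble::tibble(
    epoch = seq_along(stages),
    stage = factor(stages, levels = SLEEP_STAGES)
  )
  attr(out, "epoch_length_s") <- epoch_length_s
  class(out) <- c("hypnogram", class(out))
  out
}

#' Extract the stage sequence of a hypnogram
#'
#' @param h A `hypnogram`, a factor, or a character vector of stage labels.
#' @return Character vector of stage labels.
#' @export
stage_sequence <- function(h) {
  if (inherits(h, "hypnogram") || is.data.frame(h)) {
    as.character(h$stage)
  } else {
    as.character(h)
  }
}

#' Epoch length of a hypnogram in seconds
#' @param h A `hypnogram`.
#' @return Numeric scalar (defaults to 20 if the attribute is absent).
#' @export
epoch_length <- function(h) {
  el <- attr(h, "epoch_length_s")
  if (is.null(el)) 20 else el
}

#' Per-stage epoch counts
#' @param h A `hypnogram` or stage-label vector.
#' @return Named integer vector over `WAKE`, `NREM`, `REM`.
#' @export
stage_counts <- function(h) {
  s <- factor(stage_sequence(h), levels = SLEEP_STAGES)
  table(s)
}

#' @export
print.hypnogram <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<hypnogram: %d epochs x %gs>\n", n, epoch_length(x)))
  if (n > 0) {
    cnt <- stage_counts(x)
    cat("  ", paste(sprintf("%s=%d", names(cnt), as.integer(cnt)),
                    collapse = "  "), "\n")
  }
  NextMethod()
}

#' Read / write hypnogram label files
#'
#' Plain single-column CSV with header `stage`, one label per epoch.
#'
#' @param path File path.
#' @param epoch_length_s Epoch length in seconds for the returned hypnogram.
#' @return `read_hypnogram()` returns a [hypnogram()]; `write_hypnogram()`
#'   returns `path` invisibly.
#' @export
read_hypnogram <- function(path, epoch_length_s = 20) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"stage" %in% names(df)) {
    stop("Hypnogram CSV must have a `stage` column: ", path)
  }
  hypnogram(df$stage, epoch_length_s = epoch_length_s)
}

#' @rdname read_hypnogram
#' @param h Hypnogram to write.
#' @export
write_hypnogram <- function(h, path) {
  utils::write.csv(
    data.frame(stage = stage_sequence(h)),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Plot a hypnogram as a step trace
#'
#' @param object A `hypnogram`.
#' @param ... Unused.
#' @return A ggplot object: stage (WAKE top, REM bottom) against time in hours.
#' @export
autoplot.hypnogram <- function(object, ...) {
  el <- epoch_length(object)
  df <- tibble::tibble(
    time_h = (object$epoch - 1) * el / 3600,
    level = 4 - as.integer(factor(stage_sequence(object),
                                  levels = SLEEP_STAGES))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$level)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(breaks = 3:1, labels = SLEEP_STAGES,
                                limits = c(0.5, 3.5)) +
    ggplot2::labs(x = "Time (h)", y = NULL) +
    ggplot2::theme_minimal()
}
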