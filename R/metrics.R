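#' Stage confusion matrix
#'
#' 3x3 count matrix over (WAKE, NREM, REM); rows are the true stage, columns
#' the predicted stage.
#'
#' @param truth,pred Hypnograms (or stage-label vectors) of equal length.
#' @return 3x3 integer matrix with stage dimnames.
#' @export
confusion_matrix_stages <- function(truth, pred) {
  t_s <- stage_sequence(truth)
  p_s <- stage_sequence(pred)
  if (length(t_s) != length(p_s)) {
    stop("length mismatch: truth has ", length(t_s), " epochs, prediction ",
         length(p_s))
  }
  tab <- table(
    true = factor(t_s, levels = SLEEP_STAGES),
    pred = factor(p_s, levels = SLEEP_STAGES)
  )
  m <- matrix(as.integer(tab), 3, 3,
              dimnames = list(true = SLEEP_STAGES, pred = SLEEP_STAGES))
  m
}

#' Score a confusion matrix
#'
#' Computes overall accuracy, per-class precision/recall/F1 (a class with
#' zero precision and recall gets F1 = 0, so scores aggregate even when REM
#' is absent from a stretch), macro F1, and Cohen's kappa
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with chance agreement
#' \eqn{p_e = \sum_c \mathrm{rowsum}_c \, \mathrm{colsum}_c / N^2}. When
#' \eqn{p_e = 1} (both raters constant), kappa is 1 for perfect agreement
#' and 0 otherwise.
#'
#' @param cm 3x3 count matrix from [confusion_matrix_stages()].
#' @return A list of class `score_report`: `confusion`, `n`, `accuracy`,
#'   `per_class` (tibble of precision/recall/F1 by stage), `macro_f1`,
#'   `kappa`.
#' @examples
#' cm <- matrix(c(50, 5, 0, 10, 40, 2, 0, 5, 8), 3, 3,
#'              dimnames = list(true = SLEEP_STAGES, pred = SLEEP_STAGES))
#' score_report(cm)
#' @export
score_report <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n <= 0) stop("confusion matrix is empty")
  if (any(cm < 0) || any(abs(cm - round(cm)) > 1e-9)) {
    stop("confusion matrix must hold non-negative integer counts")
  }
  rs <- rowSums(cm)
  cs <- colSums(cm)
  diagc <- diag(cm)
  precision <- ifelse(cs > 0, diagc / cs, 0)
  recall <- ifelse(rs > 0, diagc / rs, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  p_o <- sum(diagc) / n
  p_e <- sum(rs * cs) / n^2
  kappa <- if (abs(1 - p_e) < 1e-15) {
    if (p_o >= 1 - 1e-15) 1 else 0
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  stages <- if (!is.null(rownames(cm))) rownames(cm) else
    paste0("class", seq_len(nrow(cm)))
  structure(
    list(
      confusion = cm,
      n = n,
      accuracy = p_o,
      per_class = tibble::tibble(stage = stages,
                                 precision = unname(precision),
                                 recall = unname(recall),
                                 f1 = unname(f1)),
      macro_f1 = mean(f1),
      kappa = kappa
    ),
    class = "score_report"
  )
}

#' Score predicted against true stages
#'
#' Convenience wrapper: confusion matrix then [score_report()].
#'
#' @inheritParams confusion_matrix_stages
#' @return A `score_report`.
#' @export
score_stages <- function(truth, pred) {
  score_report(confusion_matrix_stages(truth, pred))
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report: n=%d  accuracy=%.4f  macroF1=%.4f  kappa=%.4f>\n",
              x$n, x$accuracy, x$macro_f1, x$kappa))
  print(x$confusion)
  print(as.data.frame(x$per_class), row.names = FALSE)
  invisible(x)
}

#' @rdname score_report
#' @param x A `score_report`.
#' @param ... Unused.
#' @return `tidy()`: one row per class with precision/recall/F1;
#'   `glance()`: one row with `n`, `accuracy`, `macro_f1`, `kappa`.
#' @export
tidy.score_report <- function(x, ...) x$per_class

#' @rdname score_report
#' @export
glance.score_report <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy, macro_f1 = x$macro_f1,
                 kappa = x$kappa)
}

#' Plot a score report's confusion matrix
#' @param object A `score_report`.
#' @param ... Unused.
#' @return ggplot heatmap of the confusion matrix with counts annotated.
#' @export
autoplot.score_report <- function(object, ...) {
  df <- tibble::as_tibble(as.table(object$confusion))
  names(df) <- c("true", "pred", "count")
  df$true <- factor(df$true, levels = rev(SLEEP_STAGES))
  df$pred <- factor(df$pred, levels = SLEEP_STAGES)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Predicted", y = "True") +
    ggplot2::theme_minimal()
}

#' Average score reports across subjects
#'
#' The reporting unit is the animal: every scalar metric is an unweighted
#' arithmetic mean over subjects' reports (the per-subject mean is generally
#' not the score of the pooled confusion matrix, which is also returned
#' summed for reference).
#'
#' @param reports List of `score_report`s (one per subject).
#' @return A list of class `aggregate_report`: `n_subjects`, `accuracy`,
#'   `macro_f1`, `kappa`, `per_class` (mean precision/recall/F1 by stage),
#'   `pooled_confusion`, and `pooled` (the `score_report` of the summed
#'   matrix, clearly a different quantity).
#' @export
aggregate_reports <- function(reports) {
  if (length(reports) == 0) stop("no reports to aggregate")
  stopifnot(all(vapply(reports, inherits, logical(1), "score_report")))
  per_class <- purrr::map_dfr(reports, "per_class") |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(dplyr::across(c("precision", "recall", "f1"), mean),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$stage, SLEEP_STAGES))
  pooled_cm <- Reduce(`+`, purrr::map(reports, "confusion"))
  structure(
    list(
      n_subjects = length(reports),
      accuracy = mean(vapply(reports, `[[`, numeric(1), "accuracy")),
      macro_f1 = mean(vapply(reports, `[[`, numeric(1), "macro_f1")),
      kappa = mean(vapply(reports, `[[`, numeric(1), "kappa")),
      per_class = per_class,
      pooled_confusion = pooled_cm,
      pooled = score_report(pooled_cm)
    ),
    class = "aggregate_report"
  )
}

#' @export
print.aggregate_report <- function(x, ...) {
  cat(sprintf(
    "<aggregate_report: %d subjects  mean accuracy=%.4f  mean kappa=%.4f>\n",
    x$n_subjects, x$accuracy, x$kappa))
  print(as.data.frame(x$per_class), row.names = FALSE)
  invisible(x)
}

#' @rdname aggregate_reports
#' @param x An `aggregate_report`.
#' @param ... Unused.
#' @export
glance.aggregate_report <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, accuracy = x$accuracy,
                 macro_f1 = x$macro_f1, kappa = x$kappa)
}

#' Score predictions per subject and average
#'
#' @param df Data frame with columns `subject_id`, `truth`, `pred` (stage
#'   labels per epoch).
#' @return An `aggregate_report` over the subjects present.
#' @export
score_by_subject <- function(df) {
  reports <- df |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_map(~ score_stages(.x$truth, .x$pred))
  aggregate_reports(reports)
}
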