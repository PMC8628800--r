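#' Labeled image collection
#'
#' An `image_dataset` is a tibble with one row per image: `image` (list of
#' equally sized numeric matrices in \[0,1\]), `label` (stage), `subject_id`,
#' `epoch_index`, `window_s`, and `provenance` (`"real"`, `"duplicated"` or
#' `"generated"`). All dplyr verbs apply; the constructor just validates.
#'
#' @param df Data frame with the columns above.
#' @return The validated tibble with class `image_dataset`.
#' @export
image_dataset <- function(df) {
  req <- c("image", "label", "subject_id", "epoch_index", "window_s",
           "provenance")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    stop("image_dataset lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(df$label), SLEEP_STAGES)
  if (length(bad) > 0) stop("unknown stage label(s): ",
                            paste(bad, collapse = ", "))
  if (nrow(df) > 0) {
    dims <- vapply(df$image, dim, integer(2))
    if (any(dims != dims[, 1])) {
      stop("all images must share identical pixel dimensions")
    }
  }
  out <- tibble::as_tibble(df)
  class(out) <- unique(c("image_dataset", class(out)))
  out
}

#' Per-stage image counts of a dataset
#' @param ds An `image_dataset`.
#' @return Named integer vector over `WAKE`, `NREM`, `REM`.
#' @export
class_counts <- function(ds) {
  table(factor(ds$label, levels = SLEEP_STAGES))
}

#' Split a dataset by subject
#'
#' Routes every image to the training or evaluation set by its `subject_id`;
#' the two id sets must be disjoint so no subject leaks across the split.
#'
#' @param ds An `image_dataset`.
#' @param train_ids,eval_ids Character vectors of subject ids.
#' @return List with elements `train` and `eval`, both `image_dataset`s.
#' @export
split_by_subject <- function(ds, train_ids, eval_ids) {
  if (length(intersect(train_ids, eval_ids)) > 0) {
    stop("train and eval subject ids overlap: ",
         paste(intersect(train_ids, eval_ids), collapse = ", "))
  }
  known <- unique(ds$subject_id)
  unknown <- setdiff(c(train_ids, eval_ids), known)
  if (length(unknown) > 0) {
    stop("unknown subject id(s): ", paste(unknown, collapse = ", "),
         "; known ids: ", paste(known, collapse = ", "))
  }
  list(
    train = image_dataset(dplyr::filter(ds, .data$subject_id %in% train_ids)),
    eval = image_dataset(dplyr::filter(ds, .data$subject_id %in% eval_ids))
  )
}

#' Balance a stage by duplicating its images
#'
#' Replicates the images of one stage so that its count becomes
#' `factor` times the original; other stages are untouched and no pixel is
#' modified. Copies are flagged `provenance = "duplicated"`.
#'
#' @param ds An `image_dataset`.
#' @param stage Stage label to duplicate.
#' @param factor Multiplier (>= 1); `factor = 10` is the "REM x10"
#'   duplication baseline.
#' @return The augmented `image_dataset`.
#' @export
balance_with_duplicates <- function(ds, stage = "REM", factor = 10) {
  stopifnot(factor >= 1)
  sub <- dplyr::filter(ds, .data$label == stage)
  if (nrow(sub) == 0) {
    warning("stage ", stage, " absent from dataset; nothing duplicated")
    return(ds)
  }
  n_copies <- as.integer(round(factor)) - 1L
  if (n_copies == 0) return(ds)
  copies <- sub[rep(seq_len(nrow(sub)), n_copies), ]
  copies$provenance <- "duplicated"
  image_dataset(dplyr::bind_rows(ds, copies))
}

#' Balance a stage by appending generated images
#'
#' Appends GAN-generated fakes of one stage, either until that stage matches
#' the largest other class (`mode = "equalize"`) or so that the stage total
#' becomes `k` times its real count (`mode = "times_k"`; `k = 10` appends 9
#' fakes per real image, the "gan_REM*9" protocol).
#'
#' @param ds An `image_dataset`.
#' @param fakes An `image_dataset` (or tibble) of generated images, all
#'   labeled `stage` with `provenance = "generated"`.
#' @param stage Stage label being augmented.
#' @param mode `"equalize"` or `"times_k"`.
#' @param k Multiplier for `times_k`.
#' @return The augmented `image_dataset`.
#' @export
balance_with_generated <- function(ds, fakes, stage = "REM",
                                   mode = c("equalize", "times_k"), k = 10) {
  mode <- match.arg(mode)
  if (nrow(fakes) > 0 && any(fakes$label != stage)) {
    stop("all fake images must carry the target stage label ", stage)
  }
  counts <- class_counts(ds)
  n_real <- counts[[stage]]
  n_needed <- if (mode == "equalize") {
    max(max(counts[setdiff(SLEEP_STAGES, stage)]) - n_real, 0)
  } else {
    (as.integer(round(k)) - 1L) * n_real
  }
  if (n_needed == 0) return(ds)
  if (nrow(fakes) < n_needed) {
    stop("insufficient fakes: need ", n_needed, ", have ", nrow(fakes),
         " (shortfall ", n_needed - nrow(fakes), ")")
  }
  add <- fakes[seq_len(n_needed), ]
  add$provenance <- "generated"
  image_dataset(dplyr::bind_rows(ds, add))
}

#' Write / read an image dataset as PNG files plus an index CSV
#'
#' Each image is an 8-bit grayscale PNG (`pixel = round(value * 255)`);
#' `index.csv` maps filename to `subject_id`, `epoch_index`, `label`,
#' `window_s` and `provenance`.
#'
#' @param ds An `image_dataset`.
#' @param dir Directory (created if needed).
#' @return `write_image_dataset()` returns `dir` invisibly;
#'   `read_image_dataset()` returns an `image_dataset`.
#' @export
write_image_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fns <- sprintf("img_%05d_%s_e%05d.png", seq_len(nrow(ds)), ds$subject_id,
                 ds$epoch_index)
  purrr::walk(seq_len(nrow(ds)), function(i) {
    png::writePNG(round(ds$image[[i]] * 255) / 255, file.path(dir, fns[i]))
  })
  idx <- dplyr::select(tibble::as_tibble(ds), -"image")
  idx$filename <- fns
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_image_dataset
#' @export
read_image_dataset <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "index.csv"),
                         stringsAsFactors = FALSE)
  imgs <- purrr::map(idx$filename, function(f) {
    p <- png::readPNG(file.path(dir, f))
    if (length(dim(p)) == 3) p <- p[, , 1]
    p
  })
  idx$image <- imgs
  idx$filename <- NULL
  image_dataset(tibble::as_tibble(idx))
}
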