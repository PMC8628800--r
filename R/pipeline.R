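#' Pipeline run configuration
#'
#' Single source of truth for an end-to-end run: simulate (or load) signals,
#' render epoch images, train the classifier, train the GAN and retrain on
#' the augmented set, predict, filter, and score. Every stochastic stage
#' consumes a seed derived deterministically from `seed`.
#'
#' @param out_dir Run directory (created on demand).
#' @param n_subjects,n_epochs_per_subject Synthetic cohort shape.
#' @param train_subjects,eval_subjects Subject ids (defaults: first
#'   `n_train` vs the rest).
#' @param n_train Number of training subjects when ids are not given.
#' @param fs,epoch_length_s Signal sampling rate and epoch length.
#' @param epochs_per_image,window_s,image_px Imaging parameters (see
#'   [build_window_images()]).
#' @param classifier A [classifier_config()].
#' @param gan A [gan_config()] (resolution must equal `image_px`).
#' @param gan_stage Stage augmented by the GAN.
#' @param gan_steps Generator updates for the GAN stage.
#' @param augment_mode `"equalize"` or `"times_k"` (see
#'   [balance_with_generated()]).
#' @param augment_k Multiplier for `times_k`.
#' @param filter_max_bout REM-in-wake filter threshold in epochs.
#' @param seed Global integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       n_subjects = 6, n_epochs_per_subject = 200,
                       train_subjects = NULL, eval_subjects = NULL,
                       n_train = 4,
                       fs = 128, epoch_length_s = 20,
                       epochs_per_image = 1, window_s = NULL, image_px = 64,
                       classifier = NULL, gan = NULL,
                       gan_stage = "REM", gan_steps = 150,
                       augment_mode = "equalize", augment_k = 10,
                       filter_max_bout = 1, seed = 42) {
  ids <- sprintf("m%02d", seq_len(n_subjects))
  if (is.null(train_subjects)) train_subjects <- ids[seq_len(n_train)]
  if (is.null(eval_subjects)) eval_subjects <- setdiff(ids, train_subjects)
  if (is.null(classifier)) {
    classifier <- classifier_config(
      input_px = image_px, filters_per_block = c(8, 16, 32, 64, 64),
      max_epochs = 10, patience = 3, seed = seed
    )
  }
  if (is.null(gan)) {
    gan <- gan_config(resolution = image_px, base_feature_maps = 16,
                      n_critic = 3, batch_size = 16, seed = seed)
  }
  if (gan$resolution != image_px) {
    stop("gan resolution (", gan$resolution, ") must equal image_px (",
         image_px, ")")
  }
  structure(
    list(out_dir = out_dir, n_subjects = n_subjects,
         n_epochs_per_subject = n_epochs_per_subject,
         subject_ids = ids, train_subjects = train_subjects,
         eval_subjects = eval_subjects, fs = fs,
         epoch_length_s = epoch_length_s,
         epochs_per_image = epochs_per_image, window_s = window_s,
         image_px = image_px, classifier = classifier, gan = gan,
         gan_stage = gan_stage, gan_steps = gan_steps,
         augment_mode = augment_mode, augment_k = augment_k,
         filter_max_bout = filter_max_bout, seed = seed),
    class = "run_config"
  )
}

PIPELINE_STAGES <- c("simulate", "images", "train", "gan", "retrain",
                     "predict", "filter", "score")

pipeline_paths <- function(config) {
  d <- config$out_dir
  list(
    signals = file.path(d, "signals"),
    images = file.path(d, "images"),
    model = file.path(d, "models", "classifier.json"),
    model_gan = file.path(d, "models", "classifier_augmented.json"),
    gan_model = file.path(d, "models", "gan.json"),
    fakes = file.path(d, "images_generated"),
    pred = file.path(d, "predictions", "pred.csv"),
    filtered = file.path(d, "predictions", "filtered.csv"),
    scores = file.path(d, "scores", "scores.json"),
    manifest = file.path(d, "manifest.json")
  )
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop("missing artifact ", path, "; run stage '", produced_by,
         "' first")
  }
  path
}

#' Run the scoring workflow
#'
#' Executes the requested stages in workflow order -- image production,
#' labeling, classifier training, GAN training, augmented retraining,
#' prediction, smoothing, scoring -- reading inputs from disk (or from
#' earlier stages in the same call) and writing every artifact under
#' `config$out_dir`. A manifest with the config hash, the seeds and an MD5
#' digest of every artifact is written at the end; re-running with an
#' identical config reproduces identical digests.
#'
#' @param config A [run_config()].
#' @param stages Subset of
#'   `c("simulate","images","train","gan","retrain","predict","filter","score")`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown) > 0) {
    stop("unknown stage(s): ", paste(unknown, collapse = ", "),
         "; valid: ", paste(PIPELINE_STAGES, collapse = ", "))
  }
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  p <- pipeline_paths(config)
  for (d in c(p$signals, dirname(p$model), dirname(p$pred),
              dirname(p$scores))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }

  if ("simulate" %in% stages) {
    for (i in seq_len(config$n_subjects)) {
      id <- config$subject_ids[i]
      h <- simulate_hypnogram(config$n_epochs_per_subject,
                              seed = derive_seed(config$seed, 100 + i),
                              epoch_length_s = config$epoch_length_s)
      rec <- synthesize_signals(h, stage_params(fs = config$fs),
                                seed = derive_seed(config$seed, 200 + i))
      write_signal_record(rec, file.path(p$signals, paste0(id, ".csv")))
      write_hypnogram(h, file.path(p$signals, paste0(id, "_labels.csv")))
    }
  }

  if ("images" %in% stages) {
    ds <- purrr::map_dfr(config$subject_ids, function(id) {
      f <- require_artifact(file.path(p$signals, paste0(id, ".csv")),
                            "simulate")
      rec <- read_signal_record(f)
      h <- read_hypnogram(file.path(p$signals, paste0(id, "_labels.csv")),
                          config$epoch_length_s)
      build_window_images(rec, h,
                          epochs_per_image = config$epochs_per_image,
                          window_s_override = config$window_s,
                          out_px = config$image_px, subject_id = id)
    })
    write_image_dataset(image_dataset(ds), p$images)
  }

  load_split <- function() {
    require_artifact(file.path(p$images, "index.csv"), "images")
    ds <- read_image_dataset(p$images)
    split_by_subject(ds, config$train_subjects, config$eval_subjects)
  }

  if ("train" %in% stages) {
    sp <- load_split()
    model <- build_classifier(config$classifier)
    model <- train_classifier(model, sp$train, sp$eval,
                              seed = derive_seed(config$seed, 1))
    save_classifier(model, p$model)
    utils::write.csv(model$history,
                     file.path(dirname(p$model), "history.csv"),
                     row.names = FALSE)
  }

  if ("gan" %in% stages) {
    sp <- load_split()
    sub <- dplyr::filter(sp$train, .data$label == config$gan_stage)
    gan <- build_wgan_gp(config$gan)
    gan <- train_wgan(gan, image_dataset(sub), steps = config$gan_steps,
                      seed = derive_seed(config$seed, 2))
    saveRDS_json_gan(gan, p$gan_model)
  }

  if ("retrain" %in% stages) {
    gan <- load_json_gan(require_artifact(p$gan_model, "gan"))
    sp <- load_split()
    counts <- class_counts(sp$train)
    n_real <- counts[[config$gan_stage]]
    n_fakes <- if (config$augment_mode == "equalize") {
      max(max(counts) - n_real, 0)
    } else {
      (config$augment_k - 1L) * n_real
    }
    fakes <- sample_fake_images(gan, n_fakes, config$gan_stage,
                                seed = derive_seed(config$seed, 3))
    aug <- balance_with_generated(sp$train, fakes, config$gan_stage,
                                  mode = config$augment_mode,
                                  k = config$augment_k)
    model <- build_classifier(config$classifier)
    model <- train_classifier(model, aug, sp$eval,
                              seed = derive_seed(config$seed, 4))
    save_classifier(model, p$model_gan)
  }

  if ("predict" %in% stages) {
    model_path <- if (file.exists(p$model_gan)) p$model_gan else p$model
    model <- load_classifier(require_artifact(model_path, "train"))
    sp <- load_split()
    pred <- predict_stages(model, sp$eval, config$epoch_length_s)
    out <- tibble::tibble(
      subject_id = sp$eval$subject_id,
      epoch_index = sp$eval$epoch_index,
      truth = sp$eval$label,
      pred = stage_sequence(pred$hypnogram)
    )
    utils::write.csv(out, p$pred, row.names = FALSE)
  }

  if ("filter" %in% stages) {
    df <- utils::read.csv(require_artifact(p$pred, "predict"),
                          stringsAsFactors = FALSE)
    df <- df |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::mutate(pred = stage_sequence(smooth_rem_in_wake(
        hypnogram(.data$pred, config$epoch_length_s),
        max_bout = config$filter_max_bout))) |>
      dplyr::ungroup()
    utils::write.csv(df, p$filtered, row.names = FALSE)
  }

  if ("score" %in% stages) {
    src <- if (file.exists(p$filtered)) p$filtered else p$pred
    df <- utils::read.csv(require_artifact(src, "predict"),
                          stringsAsFactors = FALSE)
    agg <- score_by_subject(df)
    jsonlite::write_json(
      list(n_subjects = agg$n_subjects, accuracy = agg$accuracy,
           macro_f1 = agg$macro_f1, kappa = agg$kappa,
           per_class = agg$per_class,
           pooled_confusion = agg$pooled_confusion),
      p$scores, auto_unbox = TRUE, digits = NA
    )
  }

  # manifest: config hash + digest of every artifact under out_dir
  cfg_file <- tempfile(fileext = ".json")
  cfg_for_hash <- unclass(config)
  cfg_for_hash$out_dir <- NULL        # hash the science, not the location
  jsonlite::write_json(rapply(cfg_for_hash, unclass, how = "replace"),
                       cfg_file, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  files <- sort(list.files(config$out_dir, recursive = TRUE,
                           full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  digests <- tools::md5sum(files)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    stages_run = stages,
    artifacts = stats::setNames(
      as.list(unname(digests)),
      sub(paste0("^", config$out_dir, "/?"), "", names(digests))
    )
  )
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA)
  unlink(cfg_file)
  invisible(manifest)
}

# GAN weights as plain JSON (text-only artifact store)
saveRDS_json_gan <- function(gan, path) {
  dump_net <- function(net) {
    lapply(nn_get_params(net), function(p)
      list(W = as.vector(p$W), dim = dim(p$W), b = p$b))
  }
  jsonlite::write_json(
    list(config = unclass(gan$config), step = gan$step,
         generator = dump_net(gan$generator),
         critic = dump_net(gan$critic)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

load_json_gan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg_fields <- obj$config[setdiff(names(obj$config), "blocks")]
  gan <- build_wgan_gp(do.call(gan_config, cfg_fields))
  restore <- function(net, dump) {
    params <- lapply(seq_len(nrow_or_len(dump)), function(k) {
      p <- if (is.data.frame(dump)) dump[k, ] else dump[[k]]
      list(W = matrix(unlist(p$W), unlist(p$dim)[1], unlist(p$dim)[2]),
           b = unlist(p$b))
    })
    nn_set_params(net, params)
  }
  gan$generator <- restore(gan$generator, obj$generator)
  gan$critic <- restore(gan$critic, obj$critic)
  gan$step <- obj$step
  gan
}
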