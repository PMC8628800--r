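#' Build a synthetic multi-subject image cohort
#'
#' Simulates one hypnogram and signal record per subject under the default
#' 10:10:1 stage chain and renders labeled epoch images — the package's
#' stand-in for a multi-animal recording study. All per-subject seeds derive
#' from `seed`.
#'
#' @param n_subjects Number of synthetic animals.
#' @param epochs_per_subject Scoring epochs per animal.
#' @param seed Cohort seed.
#' @param image_px Image side length.
#' @param epochs_per_image 1 or 2 (see [build_window_images()]).
#' @return An `image_dataset` covering all subjects (`m01`, `m02`, ...).
#' @export
build_synthetic_cohort <- function(n_subjects = 6, epochs_per_subject = 333,
                                   seed = 42, image_px = 64,
                                   epochs_per_image = 1) {
  ds <- purrr::map_dfr(seq_len(n_subjects), function(i) {
    h <- simulate_hypnogram(epochs_per_subject,
                            seed = derive_seed(seed, 100 + i))
    rec <- synthesize_signals(h, seed = derive_seed(seed, 200 + i))
    build_window_images(rec, h, epochs_per_image = epochs_per_image,
                        out_px = image_px,
                        subject_id = sprintf("m%02d", i))
  })
  image_dataset(ds)
}

#' Subject-held-out classifier benchmark on synthetic data
#'
#' The package's core recovery experiment: train the stage classifier on the
#' first `n_train` subjects of a synthetic cohort and score it per held-out
#' subject (unweighted per-animal mean, the study's reporting unit).
#'
#' @param cohort An `image_dataset` from [build_synthetic_cohort()];
#'   built with the defaults when `NULL`.
#' @param n_train Leading subjects used for training; the rest are held out.
#' @param train_seed Seed for initialization/shuffling/dropout.
#' @param max_epochs,patience,filters,learning_rate,batch_size Training
#'   profile; the default is the desk-scale profile (halved VGG ladder).
#' @param train_ds Optional augmented training set overriding the cohort's
#'   training half (must not contain held-out subjects).
#' @return List: `report` (an `aggregate_report`), `model`, `predictions`
#'   (tibble of subject/truth/pred).
#' @export
synthetic_benchmark <- function(cohort = NULL, n_train = 4, train_seed = 1,
                                max_epochs = 4, patience = 2,
                                filters = c(8, 16, 32, 64, 64),
                                learning_rate = 1e-4, batch_size = 32,
                                train_ds = NULL) {
  if (is.null(cohort)) cohort <- build_synthetic_cohort()
  ids <- sort(unique(cohort$subject_id))
  sp <- split_by_subject(cohort, ids[seq_len(n_train)],
                         ids[-seq_len(n_train)])
  if (is.null(train_ds)) train_ds <- sp$train
  px <- nrow(cohort$image[[1]])
  cfg <- classifier_config(
    input_px = px, filters_per_block = filters,
    learning_rate = learning_rate, batch_size = batch_size,
    max_epochs = max_epochs, patience = patience, seed = train_seed
  )
  model <- train_classifier(build_classifier(cfg), train_ds, sp$eval,
                            seed = train_seed)
  pr <- predict_stages(model, sp$eval)
  predictions <- tibble::tibble(
    subject_id = sp$eval$subject_id,
    truth = sp$eval$label,
    pred = stage_sequence(pr$hypnogram)
  )
  list(report = score_by_subject(predictions), model = model,
       predictions = predictions)
}

#' REM augmentation comparison on an imbalanced synthetic set
#'
#' Reproduces the minority-class augmentation experiment shape: under the
#' natural ~10:10:1 imbalance, compare (a) the unaugmented baseline, (b)
#' copying REM images tenfold, and (c) appending GAN-generated fake REM
#' until the classes are equal, all scored on held-out subjects. The GAN is
#' trained once on the training subjects' real REM images and shared across
#' classifier seeds.
#'
#' @param cohort An `image_dataset`; defaults to a small two-plus-two
#'   subject cohort.
#' @param n_train Training subjects (held-out = the rest).
#' @param train_seeds Classifier seeds; results are averaged across them.
#' @param gan_steps Generator updates for the REM generator.
#' @param gan_seed Seed of the GAN build/training.
#' @param dup_factor Duplication factor for the copying baseline.
#' @param max_epochs,filters Classifier profile per condition.
#' @return List: `summary` (tibble: condition, mean REM recall/accuracy/
#'   kappa across seeds), `per_seed` (tibble with one row per condition and
#'   seed), `gan` (the trained generator).
#' @export
augmentation_benchmark <- function(cohort = NULL, n_train = 1,
                                   train_seeds = 1:3, gan_steps = 200,
                                   gan_seed = 1, dup_factor = 10,
                                   max_epochs = 2,
                                   filters = c(8, 16, 32, 64, 64)) {
  if (is.null(cohort)) {
    cohort <- build_synthetic_cohort(n_subjects = 3,
                                     epochs_per_subject = 250, seed = 42)
  }
  ids <- sort(unique(cohort$subject_id))
  sp <- split_by_subject(cohort, ids[seq_len(n_train)],
                         ids[-seq_len(n_train)])
  px <- nrow(cohort$image[[1]])
  rem_real <- image_dataset(dplyr::filter(sp$train, .data$label == "REM"))
  gan_cfg <- gan_config(resolution = px, base_feature_maps = 16,
                        n_critic = 2, batch_size = 16, seed = gan_seed)
  gan <- train_wgan(build_wgan_gp(gan_cfg), rem_real, steps = gan_steps,
                    seed = gan_seed)
  counts <- class_counts(sp$train)
  n_fakes <- max(max(counts) - counts[["REM"]], 0)
  fakes <- sample_fake_images(gan, n_fakes, "REM",
                              seed = derive_seed(gan_seed, 17))
  sets <- list(
    baseline = sp$train,
    duplicated = balance_with_duplicates(sp$train, "REM", dup_factor),
    gan = balance_with_generated(sp$train, fakes, "REM", mode = "equalize")
  )
  per_seed <- purrr::map_dfr(names(sets), function(cond) {
    purrr::map_dfr(train_seeds, function(s) {
      res <- synthetic_benchmark(cohort, n_train = n_train, train_seed = s,
                                 max_epochs = max_epochs, patience = 2,
                                 filters = filters,
                                 train_ds = sets[[cond]])
      rep <- res$report
      tibble::tibble(
        condition = cond, seed = s,
        rem_recall = rep$per_class$recall[rep$per_class$stage == "REM"],
        accuracy = rep$accuracy, kappa = rep$kappa
      )
    })
  })
  summary <- per_seed |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(dplyr::across(c("rem_recall", "accuracy", "kappa"),
                                   mean), .groups = "drop")
  list(summary = summary, per_seed = per_seed, gan = gan)
}
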