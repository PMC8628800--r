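test_that("the default architecture matches the published head: 5 blocks, dense 128..64", {
  cfg <- classifier_config()
  expect_identical(cfg$conv_blocks, 5)
  expect_identical(cfg$dense_units[1], 128)
  expect_identical(cfg$dense_units[length(cfg$dense_units)], 64)
  model <- build_classifier(classifier_config(input_px = 32,
                                              filters_per_block =
                                                c(2, 2, 2, 2, 2)))
  conv_layers <- sum(vapply(model$net$layers,
                            function(l) l$type == "conv3", logical(1)))
  pools <- sum(vapply(model$net$layers,
                      function(l) l$type == "maxpool2", logical(1)))
  drops <- sum(vapply(model$net$layers,
                      function(l) l$type == "dropout", logical(1)))
  dense <- sum(vapply(model$net$layers,
                      function(l) l$type == "dense", logical(1)))
  expect_identical(conv_layers, 10L)  # two 3x3 convs per block
  expect_identical(pools, 5L)
  expect_identical(drops, 2L)
  expect_identical(dense, 4L)         # three hidden + softmax output
})

test_that("config validation catches geometry and head errors", {
  expect_error(classifier_config(dense_units = c(64, 96, 128)),
               "non-increasing")
  expect_error(classifier_config(input_px = 16, conv_blocks = 5,
                                 filters_per_block = c(2, 2, 2, 2, 2)),
               "minimum")
  # the 180 px native size floors through five pooling levels: 180 -> 5
  m <- build_classifier(classifier_config(
    input_px = 180, filters_per_block = c(2, 2, 2, 2, 2)))
  flatten_i <- which(vapply(m$net$layers, function(l) l$type == "flatten",
                            logical(1)))
  expect_identical(m$net$layers[[flatten_i]]$in_shape, c(5, 5, 2))
})

test_that("n_classes = 5 yields 5-probability outputs", {
  cfg <- tiny_classifier_config(n_classes = 5)
  model <- build_classifier(cfg)
  model$trained <- TRUE
  imgs <- lapply(1:3, function(i) matrix(runif(32 * 32), 32, 32))
  pr <- predict_stages(model, imgs)
  expect_identical(dim(pr$probs), c(3L, 5L))
  expect_equal(rowSums(pr$probs), rep(1, 3), tolerance = 1e-6)
})

test_that("an over-capacity model memorizes a 30-image training set", {
  ds <- tiny_image_set(n_epochs = 30, seed = 51)
  cfg <- tiny_classifier_config(max_epochs = 40, patience = 1e6)
  model <- build_classifier(cfg)
  model <- train_classifier(model, ds, ds)
  expect_identical(max(model$history$train_acc), 1)
})

test_that("early stopping halts after `patience` non-improving epochs and keeps the best weights", {
  ds <- tiny_image_set(n_epochs = 40, seed = 52)
  # random validation labels: validation loss cannot keep improving
  val <- tiny_image_set(n_epochs = 20, seed = 53)
  set.seed(1)
  val$label <- sample(SLEEP_STAGES, 20, replace = TRUE)
  cfg <- tiny_classifier_config(max_epochs = 30, patience = 2)
  model <- train_classifier(build_classifier(cfg), ds, val)
  n_ep <- nrow(model$history)
  expect_lt(n_ep, 30)
  expect_identical(n_ep, model$best_epoch + 2L)
  expect_equal(model$history$val_loss[model$best_epoch],
               min(model$history$val_loss), tolerance = 1e-12)
})

test_that("training is deterministic given the seed", {
  ds <- tiny_image_set(n_epochs = 24, seed = 54)
  val <- tiny_image_set(n_epochs = 12, seed = 55)
  cfg <- tiny_classifier_config(max_epochs = 2)
  m1 <- train_classifier(build_classifier(cfg), ds, val, seed = 99)
  m2 <- train_classifier(build_classifier(cfg), ds, val, seed = 99)
  expect_identical(m1$history, m2$history)
  m3 <- train_classifier(build_classifier(cfg), ds, val, seed = 100)
  expect_false(identical(m1$history$train_loss, m3$history$train_loss))
})

test_that("degenerate training inputs are rejected", {
  ds <- tiny_image_set(n_epochs = 24, seed = 56)
  one_class <- dplyr::filter(ds, label == ds$label[1])
  cfg <- tiny_classifier_config()
  expect_error(train_classifier(build_classifier(cfg), one_class, ds),
               "single class")
  expect_error(train_classifier(build_classifier(cfg), ds[0, ], ds),
               "non-empty")
  fake_val <- ds
  fake_val$provenance <- "generated"
  expect_error(train_classifier(build_classifier(cfg), ds, fake_val),
               "evaluation set")
  big <- tiny_image_set(n_epochs = 10, seed = 57, out_px = 64)
  expect_error(train_classifier(build_classifier(cfg), big, big),
               "input_px")
})

test_that("prediction returns per-image simplex rows, empty-in empty-out, and permutes with input", {
  ds <- tiny_image_set(n_epochs = 24, seed = 58)
  val <- tiny_image_set(n_epochs = 12, seed = 59)
  model <- train_classifier(build_classifier(tiny_classifier_config()),
                            ds, val)
  pr <- predict_stages(model, val)
  expect_equal(rowSums(pr$probs), rep(1, 12), tolerance = 1e-6)
  expect_identical(nrow(pr$hypnogram), 12L)
  empty <- predict_stages(model, list())
  expect_identical(nrow(empty$hypnogram), 0L)
  perm <- c(5, 1, 12, 3, 7)
  pr2 <- predict_stages(model, val[perm, ])
  expect_equal(pr2$probs, pr$probs[perm, ], tolerance = 1e-12)
  expect_error(predict_stages(build_classifier(tiny_classifier_config()),
                              val), "untrained")
})

test_that("hidden dense activations have the configured widths", {
  # balanced labels by construction so the tiny training set is never
  # single-class
  h <- hypnogram(rep(SLEEP_STAGES, each = 8))
  rec <- synthesize_signals(h, seed = 60)
  ds <- build_window_images(rec, h, out_px = 32, subject_id = "a")
  val <- tiny_image_set(n_epochs = 12, seed = 61)
  model <- train_classifier(build_classifier(tiny_classifier_config()),
                            ds, val)
  a1 <- extract_activations(model, val, "first_dense")
  a2 <- extract_activations(model, val, "last_dense")
  expect_identical(dim(a1), c(12L, 128L))
  expect_identical(dim(a2), c(12L, 64L))
  expect_error(extract_activations(model, val, "middle_dense"),
               "first_dense")
})

test_that("weights survive a JSON save/load round trip", {
  ds <- tiny_image_set(n_epochs = 24, seed = 62)
  val <- tiny_image_set(n_epochs = 12, seed = 63)
  model <- train_classifier(build_classifier(tiny_classifier_config()),
                            ds, val)
  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(model, path)
  model2 <- load_classifier(path)
  pr1 <- predict_stages(model, val)
  pr2 <- predict_stages(model2, val)
  expect_equal(pr1$probs, pr2$probs, tolerance = 1e-12)
})

test_that("adding the preceding epoch does not cost more than 2 accuracy points (3 seeds)", {
  # weak consistency of the 2-epoch window with the 1-epoch window
  h_tr <- simulate_hypnogram(220, seed = 71)
  h_te <- simulate_hypnogram(120, seed = 72)
  rec_tr <- synthesize_signals(h_tr, seed = 73)
  rec_te <- synthesize_signals(h_te, seed = 74)
  acc <- function(epi, seed) {
    tr <- build_window_images(rec_tr, h_tr, epochs_per_image = epi,
                              out_px = 32, subject_id = "a")
    te <- build_window_images(rec_te, h_te, epochs_per_image = epi,
                              out_px = 32, subject_id = "b")
    cfg <- tiny_classifier_config(max_epochs = 3, seed = seed)
    m <- train_classifier(build_classifier(cfg), tr, te, seed = seed)
    pr <- predict_stages(m, te)
    mean(stage_sequence(pr$hypnogram) == te$label)
  }
  acc1 <- vapply(1:3, function(s) acc(1, s), numeric(1))
  acc2 <- vapply(1:3, function(s) acc(2, s), numeric(1))
  expect_gte(mean(acc2), mean(acc1) - 0.02)
})
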