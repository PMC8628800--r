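#' Classifier configuration
#'
#' Architecture and training hyper-parameters of the VGG-style stage
#' classifier: five blocks of two 3x3 convolutions plus 2x2 max pooling,
#' then a dense head 128 -> dropout -> 96 -> 64 -> dropout -> softmax. The
#' first hidden dense layer has 128 units and the last 64 under defaults;
#' those two layers are the ones whose activations can be extracted for
#' embedding analyses.
#'
#' @param input_px Image side length (must be divisible by
#'   `2^conv_blocks`).
#' @param conv_blocks Number of conv-conv-pool blocks (default 5).
#' @param filters_per_block Output channels per block. The default
#'   `c(16, 32, 64, 128, 128)` is a scaled-down VGG ladder; tests use the
#'   desk-scale halved ladder.
#' @param dense_units Hidden dense widths, non-increasing; default
#'   `c(128, 96, 64)`.
#' @param dropout_rates Two dropout rates (after the first and last hidden
#'   dense layers).
#' @param n_classes Output classes (3 stages by default; settable to 5 for
#'   human-style staging).
#' @param learning_rate,batch_size,max_epochs,patience Adam learning rate,
#'   mini-batch size, epoch cap and early-stopping patience (epochs without
#'   validation-loss improvement).
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return A validated list of class `classifier_config`.
#' @export
classifier_config <- function(input_px = 180, conv_blocks = 5,
                              filters_per_block = c(16, 32, 64, 128, 128),
                              dense_units = c(128, 96, 64),
                              dropout_rates = c(0.3, 0.3),
                              n_classes = 3, learning_rate = 1e-4,
                              batch_size = 32, max_epochs = 100,
                              patience = 10, seed = 1) {
  stopifnot(conv_blocks >= 1, n_classes >= 2,
            length(filters_per_block) == conv_blocks,
            length(dropout_rates) == 2)
  if (any(diff(dense_units) > 0)) {
    stop("dense_units must be non-increasing")
  }
  # each block halves the map (odd sizes floor); the final map must be >= 1
  min_px <- 2^conv_blocks
  if (input_px < min_px) {
    stop("input_px = ", input_px, " is too small for ", conv_blocks,
         " pooling levels (minimum ", min_px, ")")
  }
  structure(
    list(input_px = input_px, conv_blocks = conv_blocks,
         filters_per_block = filters_per_block, dense_units = dense_units,
         dropout_rates = dropout_rates, n_classes = n_classes,
         learning_rate = learning_rate, batch_size = batch_size,
         max_epochs = max_epochs, patience = patience, seed = seed),
    class = "classifier_config"
  )
}

#' Build the stage classifier
#'
#' Assembles the network of [classifier_config()] with seeded He
#' initialization. The model is untrained until [train_classifier()] is
#' called.
#'
#' @param config A [classifier_config()].
#' @return An object of class `sleep_classifier`.
#' @export
build_classifier <- function(config) {
  stopifnot(inherits(config, "classifier_config"))
  local_seed(config$seed)
  layers <- list()
  for (b in seq_len(config$conv_blocks)) {
    f <- config$filters_per_block[b]
    layers <- c(layers, list(layer_conv3(f), layer_relu(),
                             layer_conv3(f), layer_relu(),
                             layer_maxpool2()))
  }
  layers <- c(layers, list(layer_flatten()))
  nd <- length(config$dense_units)
  dense_pos <- integer(nd)
  for (k in seq_len(nd)) {
    layers <- c(layers, list(layer_dense(config$dense_units[k]),
                             layer_relu()))
    dense_pos[k] <- length(layers)          # index of the relu output
    if (k == 1) {
      layers <- c(layers, list(layer_dropout(config$dropout_rates[1])))
    }
    if (k == nd) {
      layers <- c(layers, list(layer_dropout(config$dropout_rates[2])))
    }
  }
  layers <- c(layers, list(layer_dense(config$n_classes)))
  net <- do.call(nn_sequential,
                 c(layers, list(input_shape = c(config$input_px,
                                                config$input_px, 1))))
  structure(
    list(config = config, net = net, dense_pos = dense_pos,
         trained = FALSE, history = NULL),
    class = "sleep_classifier"
  )
}

#' @export
print.sleep_classifier <- function(x, ...) {
  cat(sprintf(
    "<sleep_classifier: %dpx, %d conv blocks, dense [%s], %d classes, %s>\n",
    x$config$input_px, x$config$conv_blocks,
    paste(x$config$dense_units, collapse = ","), x$config$n_classes,
    if (x$trained) "trained" else "untrained"))
  cat(sprintf("  parameters: %d\n", nn_count_params(x$net)))
  invisible(x)
}

# image_dataset (or list of matrices) -> pixels x N batch matrix
dataset_to_matrix <- function(images) {
  imgs <- if (is.data.frame(images)) images$image else images
  if (length(imgs) == 0) return(matrix(numeric(0), 0, 0))
  do.call(cbind, lapply(imgs, as.vector))
}

labels_to_onehot <- function(labels, n_classes = 3) {
  ix <- as.integer(factor(labels, levels = SLEEP_STAGES))
  y <- matrix(0, n_classes, length(ix))
  y[cbind(ix, seq_along(ix))] <- 1
  y
}

classifier_eval <- function(model, x, y_onehot, batch = 64) {
  n <- ncol(x)
  loss <- 0
  correct <- 0
  for (s in seq(1, n, by = batch)) {
    e <- min(s + batch - 1, n)
    p <- softmax_cols(net_forward(model$net, x[, s:e, drop = FALSE]))
    yb <- y_onehot[, s:e, drop = FALSE]
    loss <- loss - sum(log(pmax(colSums(p * yb), 1e-12)))
    correct <- correct + sum(apply(p, 2, which.max) ==
                               apply(yb, 2, which.max))
  }
  list(loss = loss / n, acc = correct / n)
}

#' Train the stage classifier
#'
#' Minimizes multinomial cross-entropy with Adam on shuffled mini-batches,
#' evaluating the validation set after every epoch. Training stops when the
#' validation loss has not improved for `patience` consecutive epochs (or at
#' `max_epochs`), and the weights from the best validation epoch are kept.
#' Deterministic for a fixed seed under single-threaded BLAS.
#'
#' @param model A `sleep_classifier` from [build_classifier()].
#' @param train,val Non-empty `image_dataset`s whose image size matches the
#'   config; generated/duplicated images are allowed in `train` only.
#' @param seed Optional override of the config seed.
#' @param verbose Print one line per epoch.
#' @return The trained `sleep_classifier`, with a `history` tibble
#'   (`epoch`, `train_loss`, `train_acc`, `val_loss`, `val_acc`).
#' @export
train_classifier <- function(model, train, val, seed = NULL,
                             verbose = FALSE) {
  cfg <- model$config
  if (nrow(train) == 0 || nrow(val) == 0) {
    stop("training and validation sets must be non-empty")
  }
  if (any(val$provenance != "real")) {
    stop("generated or duplicated images must not enter an evaluation set")
  }
  px <- nrow(train$image[[1]])
  if (px != cfg$input_px || ncol(train$image[[1]]) != cfg$input_px) {
    stop("image size ", px, " does not match config input_px ",
         cfg$input_px)
  }
  if (length(unique(train$label)) < 2) {
    stop("training set holds a single class; softmax fit is degenerate")
  }
  x_tr <- dataset_to_matrix(train)
  y_tr <- labels_to_onehot(train$label, cfg$n_classes)
  x_va <- dataset_to_matrix(val)
  y_va <- labels_to_onehot(val$label, cfg$n_classes)
  local_seed(if (is.null(seed)) cfg$seed else seed)
  state <- adam_state(model$net)
  net <- model$net
  best <- list(loss = Inf, params = nn_get_params(net), epoch = 0L)
  wait <- 0L
  hist <- vector("list", cfg$max_epochs)
  n <- ncol(x_tr)
  for (ep in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    ep_correct <- 0
    for (s in seq(1, n, by = cfg$batch_size)) {
      ix <- ord[s:min(s + cfg$batch_size - 1, n)]
      xb <- x_tr[, ix, drop = FALSE]
      yb <- y_tr[, ix, drop = FALSE]
      fw <- nn_forward(net, xb, training = TRUE)
      p <- softmax_cols(fw$out)
      ep_loss <- ep_loss - sum(log(pmax(colSums(p * yb), 1e-12)))
      ep_correct <- ep_correct + sum(apply(p, 2, which.max) ==
                                       apply(yb, 2, which.max))
      bw <- nn_backward(net, fw$caches, (p - yb) / length(ix),
                        need_input_grad = FALSE)
      upd <- adam_step(net, bw$param_grads, state, cfg$learning_rate)
      net <- upd$net
      state <- upd$state
    }
    model$net <- net
    va <- classifier_eval(model, x_va, y_va)
    hist[[ep]] <- tibble::tibble(
      epoch = ep, train_loss = ep_loss / n, train_acc = ep_correct / n,
      val_loss = va$loss, val_acc = va$acc
    )
    if (verbose) {
      message(sprintf(
        "epoch %3d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
        ep, ep_loss / n, ep_correct / n, va$loss, va$acc))
    }
    if (va$loss < best$loss - 1e-9) {
      best <- list(loss = va$loss, params = nn_get_params(net), epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model$net <- nn_set_params(net, best$params)
  model$trained <- TRUE
  model$best_epoch <- best$epoch
  model$history <- dplyr::bind_rows(hist[!vapply(hist, is.null,
                                                 logical(1))])
  model
}

#' Predict stages for a set of epoch images
#'
#' @param model A trained `sleep_classifier`.
#' @param images An `image_dataset` or list of image matrices.
#' @param epoch_length_s Epoch length for the returned hypnogram.
#' @return List with `hypnogram` (argmax labels; ties break toward the
#'   earlier stage in (WAKE, NREM, REM) order) and `probs` (N x n_classes
#'   matrix, rows summing to 1).
#' @export
predict_stages <- function(model, images, epoch_length_s = 20) {
  if (!isTRUE(model$trained)) {
    stop("model is untrained; call train_classifier() first")
  }
  x <- dataset_to_matrix(images)
  if (ncol(x) == 0) {
    return(list(hypnogram = hypnogram(character(0), epoch_length_s),
                probs = matrix(numeric(0), 0, model$config$n_classes)))
  }
  if (nrow(x) != prod(model$net$layers[[1]]$in_shape)) {
    stop("image size does not match the model input")
  }
  n <- ncol(x)
  probs <- matrix(0, n, model$config$n_classes)
  for (s in seq(1, n, by = 64)) {
    e <- min(s + 63, n)
    probs[s:e, ] <- t(softmax_cols(net_forward(model$net,
                                               x[, s:e, drop = FALSE])))
  }
  if (model$config$n_classes == 3) colnames(probs) <- SLEEP_STAGES
  lab <- SLEEP_STAGES[apply(probs, 1, which.max)]
  list(hypnogram = hypnogram(lab, epoch_length_s), probs = probs)
}

#' Extract hidden dense-layer activations
#'
#' Returns the post-activation output of the first (width 128 under
#' defaults) or last (width 64) hidden dense layer, one row per image --
#' the representation used for embedding/clustering analyses of how the
#' network separates the stages.
#'
#' @param model A trained `sleep_classifier`.
#' @param images `image_dataset` or list of image matrices.
#' @param layer `"first_dense"` or `"last_dense"`.
#' @return N x width activation matrix.
#' @export
extract_activations <- function(model, images,
                                layer = c("first_dense", "last_dense")) {
  if (!isTRUE(model$trained)) stop("model is untrained")
  layer <- tryCatch(match.arg(layer), error = function(e) {
    stop("unknown layer '", layer[1],
         "'; valid layers: first_dense, last_dense")
  })
  pos <- if (layer == "first_dense") {
    model$dense_pos[1]
  } else {
    model$dense_pos[length(model$dense_pos)]
  }
  x <- dataset_to_matrix(images)
  n <- ncol(x)
  out <- NULL
  for (s in seq(1, n, by = 64)) {
    e <- min(s + 63, n)
    a <- net_forward(model$net, x[, s:e, drop = FALSE], stop_after = pos)
    out <- rbind(out, t(a))
  }
  out
}

#' @rdname train_classifier
#' @param x A `sleep_classifier`.
#' @param ... Unused.
#' @return `tidy()`: the training history in long form (`epoch`, `metric`,
#'   `split`, `value`); `glance()`: one row with parameter count, best epoch
#'   and final validation metrics.
#' @export
tidy.sleep_classifier <- function(x, ...) {
  if (is.null(x$history)) {
    stop("model has no training history yet")
  }
  tidyr::pivot_longer(x$history, -"epoch", names_to = c("split", "metric"),
                      names_sep = "_")
}

#' @rdname train_classifier
#' @export
glance.sleep_classifier <- function(x, ...) {
  tibble::tibble(
    n_parameters = nn_count_params(x$net),
    trained = x$trained,
    best_epoch = if (is.null(x$best_epoch)) NA_integer_ else x$best_epoch,
    val_loss = if (is.null(x$history)) NA_real_ else
      x$history$val_loss[x$best_epoch],
    val_acc = if (is.null(x$history)) NA_real_ else
      x$history$val_acc[x$best_epoch]
  )
}

#' Plot classifier training curves
#' @param object A trained `sleep_classifier`.
#' @param ... Unused.
#' @return ggplot of loss and accuracy per epoch for train and validation.
#' @export
autoplot.sleep_classifier <- function(object, ...) {
  df <- tidy.sleep_classifier(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Save / load a classifier's weights and config as JSON
#'
#' Plain-text container: config plus flattened parameter arrays.
#'
#' @param model A `sleep_classifier`.
#' @param path File path (JSON).
#' @return `save_classifier()` returns `path` invisibly; `load_classifier()`
#'   the restored model.
#' @export
save_classifier <- function(model, path) {
  params <- nn_get_params(model$net)
  jsonlite::write_json(
    list(
      config = unclass(model$config),
      trained = model$trained,
      best_epoch = model$best_epoch,
      params = lapply(params, function(p)
        list(W = as.vector(p$W), dim = dim(p$W), b = p$b))
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(classifier_config, obj$config)
  model <- build_classifier(cfg)
  params <- lapply(seq_len(nrow_or_len(obj$params)), function(k) {
    p <- if (is.data.frame(obj$params)) obj$params[k, ] else obj$params[[k]]
    W <- matrix(unlist(p$W), unlist(p$dim)[1], unlist(p$dim)[2])
    list(W = W, b = unlist(p$b))
  })
  model$net <- nn_set_params(model$net, params)
  model$trained <- isTRUE(obj$trained)
  model$best_epoch <- obj$best_epoch
  model
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
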