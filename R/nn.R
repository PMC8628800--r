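#' Minimal feed-forward network toolkit
#'
#' The classifier and the WGAN-GP are built on a small sequential-network
#' framework written for this package: 3x3 same-padding convolutions
#' (im2col + BLAS gemm), 2x2 max/average pooling, nearest-neighbour
#' upsampling, dense, dropout and pointwise activations, with reverse-mode
#' gradients both for the weights and for the network input (the latter is
#' what the Wasserstein gradient penalty differentiates). Batches are stored
#' one example per column; a feature map of `H x W` pixels and `C` channels
#' occupies `H*W*C` rows, channel blocks contiguous, pixels column-major.
#'
#' `nn_sequential()` assembles layers and infers every layer's input/output
#' shape from `input_shape`.
#'
#' @param ... Layers, in order.
#' @param input_shape Either `c(H, W, C)` for image input or a single integer
#'   for flat input.
#' @return An object of class `nn_net`.
#' @name nn_toolkit
NULL

#' @rdname nn_toolkit
#' @export
nn_sequential <- function(..., input_shape) {
  layers <- list(...)
  shape <- if (length(input_shape) == 3) input_shape else c(input_shape)
  for (i in seq_along(layers)) {
    layers[[i]] <- nn_build_layer(layers[[i]], shape)
    shape <- layers[[i]]$out_shape
  }
  structure(list(layers = layers, out_shape = shape), class = "nn_net")
}

#' @rdname nn_toolkit
#' @param filters Number of output channels of the convolution.
#' @export
layer_conv3 <- function(filters) list(type = "conv3", filters = filters)

#' @rdname nn_toolkit
#' @param units Number of output units of the dense layer.
#' @export
layer_dense <- function(units) list(type = "dense", units = units)

#' @rdname nn_toolkit
#' @export
layer_relu <- function() list(type = "relu")

#' @rdname nn_toolkit
#' @param alpha Negative-side slope of the leaky ReLU.
#' @export
layer_lrelu <- function(alpha = 0.2) list(type = "lrelu", alpha = alpha)

#' @rdname nn_toolkit
#' @export
layer_sigmoid <- function() list(type = "sigmoid")

#' @rdname nn_toolkit
#' @export
layer_maxpool2 <- function() list(type = "maxpool2")

#' @rdname nn_toolkit
#' @export
layer_avgpool2 <- function() list(type = "avgpool2")

#' @rdname nn_toolkit
#' @export
layer_upsample2 <- function() list(type = "upsample2")

#' @rdname nn_toolkit
#' @export
layer_flatten <- function() list(type = "flatten")

#' @rdname nn_toolkit
#' @param rate Dropout probability.
#' @export
layer_dropout <- function(rate = 0.3) list(type = "dropout", rate = rate)

#' @rdname nn_toolkit
#' @param shape Target shape `c(H, W, C)` for reshaping flat input.
#' @export
layer_reshape <- function(shape) list(type = "reshape", shape = shape)

# He-normal initialization, drawn from the current R RNG stream
he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

nn_build_layer <- function(layer, in_shape) {
  layer$in_shape <- in_shape
  flat <- prod(in_shape)
  layer$out_shape <- switch(
    layer$type,
    conv3 = {
      stopifnot(length(in_shape) == 3)
      C <- in_shape[3]
      # one column per filter: patches (HW*N x 9C) %*% W -> (HW*N x F)
      layer$W <- he_init(9 * C, layer$filters, fan_in = 9 * C)
      layer$b <- numeric(layer$filters)
      c(in_shape[1], in_shape[2], layer$filters)
    },
    dense = {
      layer$W <- he_init(layer$units, flat, fan_in = flat)
      layer$b <- numeric(layer$units)
      layer$units
    },
    maxpool2 = ,
    avgpool2 = {
      # odd dimensions drop the trailing row/column ("valid" pooling)
      stopifnot(length(in_shape) == 3, in_shape[1] >= 2, in_shape[2] >= 2)
      c(in_shape[1] %/% 2, in_shape[2] %/% 2, in_shape[3])
    },
    upsample2 = {
      stopifnot(length(in_shape) == 3)
      c(in_shape[1] * 2, in_shape[2] * 2, in_shape[3])
    },
    flatten = flat,
    reshape = {
      stopifnot(prod(layer$shape) == flat)
      layer$shape
    },
    relu = ,
    lrelu = ,
    sigmoid = ,
    dropout = in_shape,
    stop("unknown layer type: ", layer$type)
  )
  layer
}

#' Run a network forward
#'
#' @param net An `nn_net`.
#' @param x Input batch: matrix with one example per column (rows =
#'   `prod(input_shape)`).
#' @param training Activate dropout (uses the current R RNG stream).
#' @param stop_after Optional layer index; the output of that layer is
#'   returned instead of the final output.
#' @return Output batch matrix.
#' @export
net_forward <- function(net, x, training = FALSE, stop_after = NULL) {
  nn_forward(net, x, training = training, keep_cache = FALSE,
             stop_after = stop_after)$out
}

# Forward pass with optional per-layer caches for backprop.
nn_forward <- function(net, x, training = FALSE, keep_cache = TRUE,
                       stop_after = NULL) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    s <- l$in_shape
    n <- ncol(x)
    res <- switch(
      l$type,
      conv3 = {
        P <- im2col3(x, s[1], s[2], s[3])
        list(out = fold_fmap(P %*% l$W, l$b, s[1] * s[2], l$filters, n),
             cache = if (keep_cache) list(P = P))
      },
      dense = list(out = l$W %*% x + l$b,
                   cache = if (keep_cache) list(x = x)),
      relu = {
        m <- x > 0
        list(out = x * m, cache = if (keep_cache) list(m = m))
      },
      lrelu = {
        m <- (x > 0) + l$alpha * (x <= 0)
        list(out = x * m, cache = if (keep_cache) list(m = m))
      },
      sigmoid = {
        y <- 1 / (1 + exp(-x))
        list(out = y, cache = if (keep_cache) list(y = y))
      },
      maxpool2 = {
        mp <- maxpool2(x, s[1], s[2], s[3])
        list(out = mp$y, cache = if (keep_cache) list(idx = mp$idx,
                                                      in_rows = nrow(x)))
      },
      avgpool2 = list(out = avgpool2(x, s[1], s[2], s[3]), cache = NULL),
      upsample2 = list(out = upsample2(x, s[1], s[2], s[3]), cache = NULL),
      flatten = ,
      reshape = list(out = x, cache = NULL),
      dropout = {
        if (training && l$rate > 0) {
          m <- (matrix(runif(length(x)), nrow(x)) >= l$rate) / (1 - l$rate)
          list(out = x * m, cache = if (keep_cache) list(m = m))
        } else {
          list(out = x, cache = NULL)
        }
      }
    )
    x <- res$out
    caches[[i]] <- res$cache
    if (!is.null(stop_after) && i == stop_after) break
  }
  list(out = x, caches = caches)
}

# Reverse pass. `grad_out` matches the forward output. Returns the gradient
# with respect to the input and, when `need_param_grads`, a per-layer list of
# dW/db. Caches must come from nn_forward(keep_cache = TRUE) on the same
# batch.
nn_backward <- function(net, caches, grad_out, need_param_grads = TRUE,
                        need_input_grad = TRUE) {
  g <- grad_out
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    s <- l$in_shape
    n <- ncol(g)
    ca <- caches[[i]]
    switch(
      l$type,
      conv3 = {
        G <- unfold_fmap(g, s[1] * s[2], l$filters, n)
        if (need_param_grads) {
          grads[[i]] <- list(dW = crossprod(ca$P, G), db = colSums(G))
        }
        g <- if (nn_is_last_param(net, i, need_input_grad)) NULL else
          col2im3(tcrossprod(G, l$W), s[1], s[2], s[3], n)
      },
      dense = {
        if (need_param_grads) {
          grads[[i]] <- list(dW = tcrossprod(g, ca$x), db = rowSums(g))
        }
        g <- if (nn_is_last_param(net, i, need_input_grad)) NULL else
          crossprod(l$W, g)
      },
      relu = g <- g * ca$m,
      lrelu = g <- g * ca$m,
      sigmoid = g <- g * ca$y * (1 - ca$y),
      maxpool2 = g <- maxpool2_bwd(g, ca$idx, ca$in_rows),
      avgpool2 = g <- avgpool2_bwd(g, s[1], s[2], s[3]),
      upsample2 = g <- upsample2_bwd(g, s[1], s[2], s[3]),
      flatten = ,
      reshape = g,
      dropout = if (!is.null(ca)) g <- g * ca$m
    )
    if (is.null(g)) break
  }
  list(input_grad = g, param_grads = grads)
}

# Gradient of the scalar sum of outputs with respect to the input batch,
# one column per example (examples do not interact in any layer).
nn_input_grads <- function(net, x) {
  fw <- nn_forward(net, x, training = FALSE, keep_cache = TRUE)
  if (nrow(fw$out) != 1) stop("input gradients need a scalar-output net")
  bw <- nn_backward(net, fw$caches, matrix(1, 1, ncol(x)),
                    need_param_grads = FALSE)
  list(grads = bw$input_grad, out = fw$out)
}

# TRUE when no earlier layer has parameters, so the input gradient of layer
# i is not needed by anything (saves the most expensive col2im of a pass).
nn_is_last_param <- function(net, i, need_input_grad) {
  if (need_input_grad || i == 1) return(!need_input_grad && i == 1)
  !any(vapply(net$layers[seq_len(i - 1)],
              function(x) x$type %in% c("conv3", "dense"), logical(1)))
}

# ---- parameter plumbing ------------------------------------------------

nn_param_layers <- function(net) {
  which(vapply(net$layers, function(l) l$type %in% c("conv3", "dense"),
               logical(1)))
}

nn_get_params <- function(net) {
  lapply(net$layers[nn_param_layers(net)], function(l) list(W = l$W, b = l$b))
}

nn_set_params <- function(net, params) {
  idx <- nn_param_layers(net)
  for (k in seq_along(idx)) {
    net$layers[[idx[k]]]$W <- params[[k]]$W
    net$layers[[idx[k]]]$b <- params[[k]]$b
  }
  net
}

nn_count_params <- function(net) {
  sum(vapply(nn_get_params(net),
             function(p) length(p$W) + length(p$b), numeric(1)))
}

# ---- Adam --------------------------------------------------------------

adam_state <- function(net) {
  ps <- nn_get_params(net)
  list(t = 0L,
       m = lapply(ps, function(p) list(W = p$W * 0, b = p$b * 0)),
       v = lapply(ps, function(p) list(W = p$W * 0, b = p$b * 0)))
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  idx <- nn_param_layers(net)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in seq_along(idx)) {
    gk <- grads[[idx[k]]]
    if (is.null(gk)) next
    for (nm in c("W", "b")) {
      g <- gk[[if (nm == "W") "dW" else "db"]]
      state$m[[k]][[nm]] <- beta1 * state$m[[k]][[nm]] + (1 - beta1) * g
      state$v[[k]][[nm]] <- beta2 * state$v[[k]][[nm]] + (1 - beta2) * g^2
      upd <- lr * (state$m[[k]][[nm]] / bc1) /
        (sqrt(state$v[[k]][[nm]] / bc2) + eps)
      lay <- net$layers[[idx[k]]]
      lay[[nm]] <- lay[[nm]] - upd
      net$layers[[idx[k]]] <- lay
    }
  }
  list(net = net, state = state)
}

# Numerically stable column-wise softmax
softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}
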