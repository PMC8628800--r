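# Finite-difference verification of the network framework the classifier
# and GAN are built on. Everything else in the package leans on these
# gradients being right.

# Nudge all biases off zero so no pre-activation sits exactly on a ReLU
# kink (where a finite difference straddles two subgradients).
randomize_biases <- function(net) {
  for (i in sleepstager:::nn_param_layers(net)) {
    net$layers[[i]]$b <- rnorm(length(net$layers[[i]]$b), sd = 0.05)
  }
  net
}

fd_param_check <- function(net, x, y, n_probe = 5) {
  loss_fn <- function(nn) {
    p <- sleepstager:::softmax_cols(net_forward(nn, x))
    -sum(log(colSums(p * y)))
  }
  fw <- sleepstager:::nn_forward(net, x)
  p <- sleepstager:::softmax_cols(fw$out)
  bw <- sleepstager:::nn_backward(net, fw$caches, p - y)
  params <- sleepstager:::nn_get_params(net)
  idx <- sleepstager:::nn_param_layers(net)
  worst <- 0
  for (k in seq_along(idx)) {
    g <- bw$param_grads[[idx[k]]]
    for (nm in c("W", "b")) {
      v <- params[[k]][[nm]]
      gv <- g[[if (nm == "W") "dW" else "db"]]
      probes <- round(seq(1, length(v), length.out = min(n_probe,
                                                         length(v))))
      for (i in probes) {
        eps <- 1e-6
        pp <- params
        pp[[k]][[nm]][i] <- v[i] + eps
        lp <- loss_fn(sleepstager:::nn_set_params(net, pp))
        pp[[k]][[nm]][i] <- v[i] - eps
        lm <- loss_fn(sleepstager:::nn_set_params(net, pp))
        fd <- (lp - lm) / (2 * eps)
        worst <- max(worst, abs(fd - gv[i]) / max(abs(fd), 1e-6))
      }
    }
  }
  worst
}

test_that("weight gradients match central finite differences on a conv/pool/dense net", {
  set.seed(42)
  net <- nn_sequential(
    layer_conv3(3), layer_relu(), layer_maxpool2(),
    layer_conv3(4), layer_lrelu(0.2), layer_avgpool2(),
    layer_flatten(), layer_dense(5), layer_relu(), layer_dense(2),
    input_shape = c(8, 8, 1)
  )
  net <- randomize_biases(net)
  x <- matrix(rnorm(64 * 3), 64, 3)
  y <- sleepstager:::labels_to_onehot(c("WAKE", "NREM", "REM"))[1:2, ]
  y <- rbind(y, 0)[1:2, ]  # 2-class one-hot
  y <- matrix(c(1, 0, 0, 1, 1, 0), 2, 3)
  expect_lt(fd_param_check(net, x, y), 1e-5)
})

test_that("weight gradients are exact through upsample/sigmoid generator-style stacks", {
  set.seed(43)
  net <- nn_sequential(
    layer_dense(4 * 4 * 2), layer_relu(), layer_reshape(c(4, 4, 2)),
    layer_upsample2(), layer_conv3(2), layer_lrelu(),
    layer_conv3(1), layer_sigmoid(), layer_flatten(), layer_dense(2),
    input_shape = 6
  )
  net <- randomize_biases(net)
  x <- matrix(rnorm(6 * 3), 6, 3)
  y <- matrix(c(1, 0, 0, 1, 1, 0), 2, 3)
  expect_lt(fd_param_check(net, x, y), 1e-5)
})

test_that("input gradients of a scalar critic match finite differences", {
  set.seed(44)
  net <- nn_sequential(
    layer_conv3(2), layer_lrelu(), layer_avgpool2(),
    layer_flatten(), layer_dense(1),
    input_shape = c(4, 4, 2)
  )
  x <- matrix(rnorm(32 * 3), 32, 3)
  g <- sleepstager:::nn_input_grads(net, x)$grads
  eps <- 1e-6
  for (i in seq(1, 32, by = 5)) {
    for (j in 1:3) {
      xp <- x; xp[i, j] <- xp[i, j] + eps
      xm <- x; xm[i, j] <- xm[i, j] - eps
      fd <- (net_forward(net, xp)[1, j] - net_forward(net, xm)[1, j]) /
        (2 * eps)
      expect_equal(g[i, j], fd, tolerance = 1e-5)
    }
  }
})

test_that("examples in a batch do not interact: outputs permute with the batch", {
  set.seed(45)
  net <- nn_sequential(layer_conv3(2), layer_relu(), layer_maxpool2(),
                       layer_flatten(), layer_dense(3),
                       input_shape = c(4, 4, 1))
  x <- matrix(rnorm(16 * 5), 16, 5)
  out <- net_forward(net, x)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(net_forward(net, x[, perm]), out[, perm],
               tolerance = 1e-12)
})

test_that("Adam steps reduce the loss of a small regression", {
  set.seed(46)
  net <- nn_sequential(layer_dense(8), layer_relu(), layer_dense(1),
                       input_shape = 4)
  x <- matrix(rnorm(4 * 64), 4, 64)
  target <- matrix(colSums(x^2), 1, 64)
  state <- sleepstager:::adam_state(net)
  loss0 <- mean((net_forward(net, x) - target)^2)
  for (i in 1:100) {
    fw <- sleepstager:::nn_forward(net, x)
    bw <- sleepstager:::nn_backward(net, fw$caches,
                                    2 * (fw$out - target) / 64,
                                    need_input_grad = FALSE)
    upd <- sleepstager:::adam_step(net, bw$param_grads, state, 1e-2)
    net <- upd$net
    state <- upd$state
  }
  expect_lt(mean((net_forward(net, x) - target)^2), loss0 / 2)
})

test_that("shape inference handles odd pooling sizes and rejects impossible stacks", {
  # odd dimensions floor ("valid" pooling); size-1 maps cannot pool
  net <- nn_sequential(layer_maxpool2(), input_shape = c(5, 5, 1))
  expect_identical(net$out_shape, c(2, 2, 1))
  expect_error(nn_sequential(layer_maxpool2(), input_shape = c(1, 4, 1)))
  expect_error(nn_sequential(layer_reshape(c(3, 3, 1)), input_shape = 8))
  expect_error(nn_sequential(list(type = "perceptron"), input_shape = 4),
               "unknown layer type")
})

test_that("dropout is active only in training mode and seeded", {
  set.seed(47)
  net <- nn_sequential(layer_dropout(0.5), input_shape = 10)
  x <- matrix(1, 10, 4)
  expect_identical(net_forward(net, x), x)
  set.seed(1)
  a <- net_forward(net, x, training = TRUE)
  set.seed(1)
  b <- net_forward(net, x, training = TRUE)
  expect_identical(a, b)
  expect_true(any(a == 0))
  expect_true(all(a %in% c(0, 2)))  # inverted scaling 1/(1-p)
})
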