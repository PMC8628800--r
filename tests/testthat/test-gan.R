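test_that("the doubling upsample chain fixes the block count: 512->7, 128->5, 64->4", {
  expect_identical(gan_config(resolution = 512)$blocks, 7L)
  expect_identical(gan_config(resolution = 128)$blocks, 5L)
  expect_identical(gan_config(resolution = 64)$blocks, 4L)
  gan <- build_wgan_gp(gan_config(resolution = 64, base_feature_maps = 8))
  expect_identical(n_generator_blocks(gan), 4L)
  ups <- sum(vapply(gan$generator$layers,
                    function(l) l$type == "upsample2", logical(1)))
  expect_identical(ups, 4L)
  expect_identical(gan$generator$out_shape, c(64, 64, 1))
  # Wasserstein critic: scalar linear output, no sigmoid
  last <- gan$critic$layers[[length(gan$critic$layers)]]
  expect_identical(last$type, "dense")
  expect_identical(last$units, 1)
  expect_error(gan_config(resolution = 100), "4 \\* 2\\^blocks")
  expect_error(gan_config(resolution = 64, gp_lambda = 0))
})

test_that("generator output lives in [0,1] at the configured resolution, seeded", {
  gan <- build_wgan_gp(gan_config(resolution = 32, base_feature_maps = 8,
                                  seed = 5))
  f1 <- sample_fake_images(gan, 4, "REM", seed = 3)
  f2 <- sample_fake_images(gan, 4, "REM", seed = 3)
  expect_identical(f1$image, f2$image)
  expect_identical(dim(f1$image[[1]]), c(32L, 32L))
  expect_true(all(unlist(f1$image) >= 0 & unlist(f1$image) <= 1))
  expect_identical(unique(f1$provenance), "generated")
  expect_identical(unique(f1$label), "REM")
  expect_identical(nrow(sample_fake_images(gan, 0, "REM")), 0L)
  expect_error(sample_fake_images(gan, -1, "REM"), ">= 0")
})

test_that("gradient penalty reproduces both closed forms exactly", {
  px <- 2
  set.seed(8)
  real <- matrix(runif(px^2 * 6), px^2, 6)
  fake <- matrix(runif(px^2 * 6), px^2, 6)
  # critic(x) = sum of pixels: ||grad|| = sqrt(n_pixels) = 2 everywhere
  crit_sum <- nn_sequential(layer_flatten(), layer_dense(1),
                            input_shape = c(px, px, 1))
  crit_sum$layers[[2]]$W[] <- 1
  crit_sum$layers[[2]]$b[] <- 0
  gp <- gradient_penalty(crit_sum, real, fake, gp_lambda = 10, seed = 1)
  expect_equal(as.numeric(gp), 10 * (sqrt(px^2) - 1)^2, tolerance = 1e-12)
  expect_equal(unname(attr(gp, "grad_norms")), rep(2, 6),
               tolerance = 1e-12)
  # constant critic: zero gradient, penalty = lambda
  crit_const <- nn_sequential(layer_flatten(), layer_dense(1),
                              input_shape = c(px, px, 1))
  crit_const$layers[[2]]$W[] <- 0
  crit_const$layers[[2]]$b[] <- 7
  gp0 <- gradient_penalty(crit_const, real, fake, gp_lambda = 3.5,
                          seed = 1)
  expect_equal(as.numeric(gp0), 3.5, tolerance = 1e-12)
  expect_error(gradient_penalty(crit_sum, real, fake[, 1:3]),
               "identical shapes")
})

test_that("interpolate gradients of a random small critic match a finite-difference oracle", {
  set.seed(9)
  crit <- nn_sequential(layer_conv3(2), layer_lrelu(0.2), layer_avgpool2(),
                        layer_flatten(), layer_dense(1),
                        input_shape = c(8, 8, 1))
  real <- matrix(runif(64 * 4), 64, 4)
  fake <- matrix(runif(64 * 4), 64, 4)
  gp <- gradient_penalty(crit, real, fake, gp_lambda = 10, seed = 2)
  xh <- attr(gp, "interpolates")
  norms <- attr(gp, "grad_norms")
  eps <- 1e-5
  fd_norms <- vapply(seq_len(ncol(xh)), function(j) {
    g <- vapply(seq_len(nrow(xh)), function(i) {
      xp <- xh; xp[i, j] <- xp[i, j] + eps
      xm <- xh; xm[i, j] <- xm[i, j] - eps
      (net_forward(crit, xp)[1, j] - net_forward(crit, xm)[1, j]) /
        (2 * eps)
    }, numeric(1))
    sqrt(sum(g^2))
  }, numeric(1))
  expect_equal(norms, fd_norms, tolerance = 1e-3)
  expect_equal(as.numeric(gp), 10 * mean((fd_norms - 1)^2),
               tolerance = 1e-3)
})

test_that("training bookkeeping: zero steps is identity, trace length is steps x n_critic", {
  ds32 <- tiny_image_set(n_epochs = 30, seed = 81, out_px = 32)
  rem_like <- ds32
  rem_like$label <- "REM"
  cfg <- gan_config(resolution = 32, base_feature_maps = 8, n_critic = 3,
                    batch_size = 8, seed = 1)
  gan <- build_wgan_gp(cfg)
  gan0 <- train_wgan(gan, rem_like, steps = 0)
  expect_identical(sleepstager:::nn_get_params(gan0$generator),
                   sleepstager:::nn_get_params(gan$generator))
  gan2 <- train_wgan(gan, rem_like, steps = 4, seed = 2)
  expect_identical(nrow(gan2$history), 4L * 3L)
  expect_identical(nrow(gan2$gen_history), 4L)
  expect_identical(gan2$step, 4L)
  mixed <- ds32
  mixed$label <- rep(c("WAKE", "REM"), length.out = nrow(mixed))
  expect_error(train_wgan(gan, mixed, steps = 1), "mixed-stage")
})

test_that("the penalty pushes critic gradient norms toward 1 during smoke training", {
  # desk-scale run: the mean |grad|-deviation from 1 at interpolates must
  # shrink relative to the first update
  h <- hypnogram(rep("REM", 60))
  rec <- synthesize_signals(h, seed = 91)
  ds <- build_window_images(rec, h, out_px = 32, subject_id = "g")
  cfg <- gan_config(resolution = 32, base_feature_maps = 8, n_critic = 2,
                    batch_size = 8, seed = 1)
  gan <- train_wgan(build_wgan_gp(cfg), ds, steps = 40, seed = 1)
  dev_first <- abs(gan$history$mean_grad_norm[1] - 1)
  dev_last <- abs(mean(utils::tail(gan$history$mean_grad_norm, 5)) - 1)
  expect_lt(dev_last, dev_first)
})

test_that("the gradient penalty decreases early in training for most seeds", {
  h <- hypnogram(rep("REM", 40))
  rec <- synthesize_signals(h, seed = 92)
  ds <- build_window_images(rec, h, out_px = 32, subject_id = "g")
  drops <- vapply(1:3, function(s) {
    cfg <- gan_config(resolution = 32, base_feature_maps = 8, n_critic = 2,
                      batch_size = 8, seed = s)
    gan <- train_wgan(build_wgan_gp(cfg), ds, steps = 25, seed = s)
    first <- mean(utils::head(gan$history$gp, 4))
    last <- mean(utils::tail(gan$history$gp, 4))
    last < first
  }, logical(1))
  expect_gte(sum(drops), 2)
})

test_that("smoke-trained fakes inherit the REM theta-band brightness profile", {
  h <- hypnogram(rep("REM", 80))
  rec <- synthesize_signals(h, seed = 93)
  ds <- build_window_images(rec, h, out_px = 32, subject_id = "g")
  cfg <- gan_config(resolution = 32, base_feature_maps = 8, n_critic = 2,
                    batch_size = 16, seed = 2)
  gan <- train_wgan(build_wgan_gp(cfg), ds, steps = 300, seed = 2)
  fakes <- sample_fake_images(gan, 64, "REM", seed = 3)
  profile <- function(imgs) {
    rowMeans(vapply(imgs, function(m) rowMeans(m[17:32, , drop = FALSE]),
                    numeric(16)))
  }
  r <- stats::cor(profile(ds$image), profile(fakes$image))
  expect_gte(r, 0.5)
})
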