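#' WGAN-GP configuration
#'
#' Wasserstein GAN with gradient penalty for synthesizing fake stage images.
#' The generator projects the latent vector to a 4x4 seed map and doubles the
#' resolution per upsample-conv block, so a resolution of `4 * 2^k` needs `k`
#' blocks: 5 blocks produce 128x128 and two further blocks reach the 512x512
#' ceiling; the desk-scale default used throughout the tests is 64 (4
#' blocks). The critic mirrors the generator with conv + average-pool
#' downsampling and ends in a single linear unit (a Wasserstein critic has no
#' sigmoid).
#'
#' @param resolution Output side length; must equal `4 * 2^blocks`.
#' @param latent_dim Latent dimension (default 100).
#' @param base_feature_maps Channel width scale; the generator's seed map has
#'   `2 * base_feature_maps` channels.
#' @param gp_lambda Gradient-penalty weight (> 0, default 10).
#' @param n_critic Critic updates per generator update (default 5).
#' @param batch_size Mini-batch size.
#' @param lr_g,lr_c Generator / critic Adam learning rates (Adam betas 0
#'   and 0.9, the standard WGAN-GP recipe; equal rates of 5e-4 let the
#'   generator track the critic within short training budgets).
#' @param seed Integer seed.
#' @return A validated list of class `gan_config`.
#' @export
gan_config <- function(resolution = 512, latent_dim = 100,
                       base_feature_maps = 32, gp_lambda = 10, n_critic = 5,
                       batch_size = 32, lr_g = 5e-4, lr_c = 5e-4, seed = 1) {
  blocks <- log2(resolution / 4)
  if (resolution < 8 || abs(blocks - round(blocks)) > 1e-9) {
    stop("resolution must be 4 * 2^blocks for integer blocks >= 1 (got ",
         resolution, ")")
  }
  stopifnot(gp_lambda > 0, n_critic >= 1, latent_dim >= 1)
  structure(
    list(resolution = resolution, blocks = as.integer(round(blocks)),
         latent_dim = latent_dim, base_feature_maps = base_feature_maps,
         gp_lambda = gp_lambda, n_critic = n_critic,
         batch_size = batch_size, lr_g = lr_g, lr_c = lr_c, seed = seed),
    class = "gan_config"
  )
}

gan_channel_plan <- function(config) {
  f0 <- 2 * config$base_feature_maps
  gen <- pmax(f0 %/% 2^seq_len(config$blocks), 8)
  list(seed_maps = f0, gen = gen, critic = rev(gen))
}

#' Build a WGAN-GP model
#'
#' @param config A [gan_config()].
#' @return An object of class `wgan_gp` holding the generator (latent ->
#'   image in \[0,1\]), the critic (image -> scalar), the config and a step
#'   counter.
#' @export
build_wgan_gp <- function(config) {
  stopifnot(inherits(config, "gan_config"))
  local_seed(config$seed)
  plan <- gan_channel_plan(config)
  gen_layers <- list(layer_dense(4 * 4 * plan$seed_maps), layer_relu(),
                     layer_reshape(c(4, 4, plan$seed_maps)))
  for (b in seq_len(config$blocks)) {
    gen_layers <- c(gen_layers, list(layer_upsample2(),
                                     layer_conv3(plan$gen[b]),
                                     layer_relu()))
  }
  gen_layers <- c(gen_layers, list(layer_conv3(1), layer_sigmoid()))
  generator <- do.call(nn_sequential,
                       c(gen_layers, list(input_shape = config$latent_dim)))
  crit_layers <- list()
  for (b in seq_len(config$blocks)) {
    crit_layers <- c(crit_layers, list(layer_conv3(plan$critic[b]),
                                       layer_lrelu(0.2),
                                       layer_avgpool2()))
  }
  crit_layers <- c(crit_layers, list(layer_flatten(), layer_dense(1)))
  critic <- do.call(nn_sequential,
                    c(crit_layers,
                      list(input_shape = c(config$resolution,
                                           config$resolution, 1))))
  structure(
    list(generator = generator, critic = critic, config = config,
         step = 0L, history = NULL),
    class = "wgan_gp"
  )
}

#' @export
print.wgan_gp <- function(x, ...) {
  cat(sprintf(
    "<wgan_gp: %dx%d (%d blocks), latent %d, lambda=%g, steps trained: %d>\n",
    x$config$resolution, x$config$resolution, x$config$blocks,
    x$config$latent_dim, x$config$gp_lambda, x$step))
  invisible(x)
}

#' Number of generator upsampling blocks
#' @param gan A `wgan_gp`.
#' @return Integer block count (`log2(resolution / 4)`).
#' @export
n_generator_blocks <- function(gan) gan$config$blocks

#' Wasserstein gradient penalty
#'
#' For each real/fake pair, draws `u ~ Uniform(0,1)`, forms the interpolate
#' `x_hat = u * real + (1 - u) * fake`, and returns
#' `gp_lambda * mean((||grad_x critic(x_hat)||_2 - 1)^2)` -- the soft unit
#' gradient-norm (Lipschitz) constraint on the critic.
#'
#' @param critic An `nn_net` with scalar output (e.g. `gan$critic`).
#' @param real_batch,fake_batch Matrices with one flattened image per
#'   column, identical shapes.
#' @param gp_lambda Penalty weight.
#' @param seed Seed for the interpolation draws.
#' @return Scalar penalty; attributes `grad_norms` (per-pair gradient norms)
#'   and `interpolates` are attached for diagnostics.
#' @export
gradient_penalty <- function(critic, real_batch, fake_batch, gp_lambda = 10,
                             seed = 1) {
  if (!all(dim(real_batch) == dim(fake_batch))) {
    stop("real and fake batches must have identical shapes: ",
         paste(dim(real_batch), collapse = "x"), " vs ",
         paste(dim(fake_batch), collapse = "x"))
  }
  local_seed(seed)
  u <- runif(ncol(real_batch))
  xh <- sweep(real_batch, 2, u, "*") + sweep(fake_batch, 2, 1 - u, "*")
  g <- nn_input_grads(critic, xh)$grads
  norms <- sqrt(colSums(g^2))
  out <- gp_lambda * mean((norms - 1)^2)
  attr(out, "grad_norms") <- norms
  attr(out, "interpolates") <- xh
  out
}

# Gradient of the penalty with respect to the critic parameters, by the
# central-difference Hessian-vector-product identity: with
# g_i = grad_x c(xh_i) held constant,  d/dw sum_i v_i' g_i(w)
# = [grad_w sum_i c(xh_i + eps v_i) - grad_w sum_i c(xh_i - eps v_i)] / 2eps.
gp_param_grads <- function(critic, xh, gp_lambda) {
  n <- ncol(xh)
  g <- nn_input_grads(critic, xh)$grads
  norms <- sqrt(colSums(g^2))
  coef <- gp_lambda * 2 * (norms - 1) / pmax(norms, 1e-12) / n
  v <- sweep(g, 2, coef, "*")
  vscale <- sqrt(mean(colSums(v^2)))
  eps <- 1e-3 / max(vscale, 1e-12)
  ones <- matrix(1, 1, n)
  fw_p <- nn_forward(critic, xh + eps * v)
  gr_p <- nn_backward(critic, fw_p$caches, ones,
                      need_input_grad = FALSE)$param_grads
  fw_m <- nn_forward(critic, xh - eps * v)
  gr_m <- nn_backward(critic, fw_m$caches, ones,
                      need_input_grad = FALSE)$param_grads
  grads <- vector("list", length(gr_p))
  for (i in seq_along(gr_p)) {
    if (!is.null(gr_p[[i]])) {
      grads[[i]] <- list(dW = (gr_p[[i]]$dW - gr_m[[i]]$dW) / (2 * eps),
                         db = (gr_p[[i]]$db - gr_m[[i]]$db) / (2 * eps))
    }
  }
  list(grads = grads, penalty = gp_lambda * mean((norms - 1)^2),
       norms = norms)
}

add_param_grads <- function(a, b, scale_b = 1) {
  for (i in seq_along(b)) {
    if (is.null(b[[i]])) next
    if (is.null(a[[i]])) {
      a[[i]] <- list(dW = b[[i]]$dW * scale_b, db = b[[i]]$db * scale_b)
    } else {
      a[[i]]$dW <- a[[i]]$dW + b[[i]]$dW * scale_b
      a[[i]]$db <- a[[i]]$db + b[[i]]$db * scale_b
    }
  }
  a
}

#' Train a WGAN-GP on single-stage images
#'
#' Per generator step, the critic is updated `n_critic` times on fresh
#' mini-batches, minimizing `mean(critic(fake)) - mean(critic(real))` plus
#' the gradient penalty; the generator then maximizes `mean(critic(fake))`.
#' Both use Adam with betas (0, 0.9). All images must carry the same stage
#' label: the augmentation design is one generator per stage, not a
#' conditional model.
#'
#' @param gan A `wgan_gp` from [build_wgan_gp()].
#' @param images `image_dataset` (single stage, image size =
#'   `config$resolution`) or a pixels x N matrix.
#' @param steps Number of generator updates.
#' @param seed Optional seed override.
#' @param verbose Print progress every 25 steps.
#' @return The trained `wgan_gp`; `$history` holds one row per critic update
#'   (`step`, `critic_update`, `critic_loss`, `gp`, `mean_grad_norm`) and
#'   `$gen_history` one row per generator update.
#' @export
train_wgan <- function(gan, images, steps, seed = NULL, verbose = FALSE) {
  cfg <- gan$config
  if (is.data.frame(images)) {
    if (length(unique(images$label)) > 1) {
      stop("mixed-stage input: train one generator per stage")
    }
    x <- dataset_to_matrix(images)
  } else {
    x <- images
  }
  if (nrow(x) != cfg$resolution^2) {
    stop("image size does not match config resolution ", cfg$resolution)
  }
  if (steps == 0) return(gan)
  local_seed(if (is.null(seed)) cfg$seed else seed)
  st_c <- if (is.null(gan$adam_c)) adam_state(gan$critic) else gan$adam_c
  st_g <- if (is.null(gan$adam_g)) adam_state(gan$generator) else gan$adam_g
  n <- ncol(x)
  bs <- min(cfg$batch_size, n)
  hist <- vector("list", steps * cfg$n_critic)
  ghist <- vector("list", steps)
  hk <- 0L
  for (s in seq_len(steps)) {
    for (k in seq_len(cfg$n_critic)) {
      xr <- x[, sample.int(n, bs), drop = FALSE]
      z <- matrix(rnorm(cfg$latent_dim * bs), cfg$latent_dim)
      xf <- net_forward(gan$generator, z)
      # Wasserstein terms
      fw_r <- nn_forward(gan$critic, xr)
      gr_r <- nn_backward(gan$critic, fw_r$caches,
                          matrix(-1 / bs, 1, bs),
                          need_input_grad = FALSE)$param_grads
      fw_f <- nn_forward(gan$critic, xf)
      gr_f <- nn_backward(gan$critic, fw_f$caches,
                          matrix(1 / bs, 1, bs),
                          need_input_grad = FALSE)$param_grads
      # gradient penalty at interpolates
      u <- runif(bs)
      xh <- sweep(xr, 2, u, "*") + sweep(xf, 2, 1 - u, "*")
      pen <- gp_param_grads(gan$critic, xh, cfg$gp_lambda)
      grads <- add_param_grads(add_param_grads(gr_r, gr_f), pen$grads)
      upd <- adam_step(gan$critic, grads, st_c, cfg$lr_c,
                       beta1 = 0, beta2 = 0.9)
      gan$critic <- upd$net
      st_c <- upd$state
      hk <- hk + 1L
      hist[[hk]] <- tibble::tibble(
        step = gan$step + s, critic_update = k,
        critic_loss = mean(fw_f$out) - mean(fw_r$out) + pen$penalty,
        gp = pen$penalty, mean_grad_norm = mean(pen$norms)
      )
    }
    # generator update: maximize mean critic(fake)
    z <- matrix(rnorm(cfg$latent_dim * bs), cfg$latent_dim)
    fw_g <- nn_forward(gan$generator, z)
    fw_c <- nn_forward(gan$critic, fw_g$out)
    dxf <- nn_backward(gan$critic, fw_c$caches, matrix(-1 / bs, 1, bs),
                       need_param_grads = FALSE)$input_grad
    gr_g <- nn_backward(gan$generator, fw_g$caches, dxf,
                        need_input_grad = FALSE)$param_grads
    updg <- adam_step(gan$generator, gr_g, st_g, cfg$lr_g,
                      beta1 = 0, beta2 = 0.9)
    gan$generator <- updg$net
    st_g <- updg$state
    ghist[[s]] <- tibble::tibble(step = gan$step + s,
                                 gen_loss = -mean(fw_c$out))
    if (verbose && s %% 25 == 0) {
      message(sprintf("step %4d  critic %.4f  gp %.4f  |grad| %.3f",
                      gan$step + s, hist[[hk]]$critic_loss,
                      hist[[hk]]$gp, hist[[hk]]$mean_grad_norm))
    }
  }
  gan$step <- as.integer(gan$step + steps)
  gan$adam_c <- st_c
  gan$adam_g <- st_g
  gan$history <- dplyr::bind_rows(gan$history, dplyr::bind_rows(hist))
  gan$gen_history <- dplyr::bind_rows(gan$gen_history,
                                      dplyr::bind_rows(ghist))
  gan
}

#' Sample fake stage images from a trained generator
#'
#' @param gan A `wgan_gp`.
#' @param n Number of images (>= 0). `9 * n_real` fakes appended to `n_real`
#'   real images is the "gan_REM*9" augmentation quantum.
#' @param stage_label Stage carried by the sampled images.
#' @param seed Seed for the latent draws.
#' @return An `image_dataset` of `n` generated images (`provenance =
#'   "generated"`, pixels in \[0,1\]).
#' @export
sample_fake_images <- function(gan, n, stage_label = "REM", seed = 1) {
  if (n < 0) stop("n must be >= 0")
  cfg <- gan$config
  px <- cfg$resolution
  imgs <- list()
  if (n > 0) {
    local_seed(seed)
    z <- matrix(rnorm(cfg$latent_dim * n), cfg$latent_dim)
    imgs <- vector("list", n)
    for (s in seq(1, n, by = 64)) {
      e <- min(s + 63, n)
      xf <- net_forward(gan$generator, z[, s:e, drop = FALSE])
      for (j in s:e) imgs[[j]] <- matrix(xf[, j - s + 1], px, px)
    }
  }
  image_dataset(tibble::tibble(
    image = imgs,
    label = rep(stage_label, n),
    subject_id = rep("generated", n),
    epoch_index = seq_len(n),
    window_s = rep(NA_real_, n),
    provenance = rep("generated", n)
  ))
}

#' @rdname train_wgan
#' @param x A `wgan_gp`.
#' @param ... Unused.
#' @return `tidy()`: the critic-update history; `glance()`: one row with
#'   step count and the mean of the last 25 critic losses / penalties.
#' @export
tidy.wgan_gp <- function(x, ...) {
  if (is.null(x$history)) stop("GAN has no training history yet")
  x$history
}

#' @rdname train_wgan
#' @export
glance.wgan_gp <- function(x, ...) {
  h <- x$history
  tail_h <- if (is.null(h)) NULL else utils::tail(h, 25)
  tibble::tibble(
    steps = x$step,
    critic_loss = if (is.null(tail_h)) NA_real_ else mean(tail_h$critic_loss),
    gp = if (is.null(tail_h)) NA_real_ else mean(tail_h$gp),
    mean_grad_norm = if (is.null(tail_h)) NA_real_ else
      mean(tail_h$mean_grad_norm)
  )
}

#' Plot WGAN-GP training traces
#' @param object A trained `wgan_gp`.
#' @param ... Unused.
#' @return ggplot of critic loss and gradient penalty per critic update.
#' @export
autoplot.wgan_gp <- function(object, ...) {
  h <- tidy.wgan_gp(object)
  h$update <- seq_len(nrow(h))
  df <- tidyr::pivot_longer(h[, c("update", "critic_loss", "gp")],
                            -"update", names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$update, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::theme_minimal()
}
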