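# Convolutional variational autoencoder: the perceptual-compression stage.
# Encoder: four convolutions (two stride-(1,2) resizing layers, then two
# 2x2-stride downsamplers), batch norm + LeakyReLU throughout, followed by a
# bilinear resize onto the g x g latent grid and a 1x1 convolution emitting
# the posterior mean and log-variance channels. Decoder mirrors it with five
# transposed convolutions and a final tanh. Strided convolution alone cannot
# land exactly on g x g from an arbitrary input shape, hence the in-network
# resize (and its mirror in the decoder).

LOGVAR_CLAMP <- 8

#' VAE configuration
#'
#' @param input_shape image `c(height, width)`; default the 200 x 794
#'   preprocessing standard.
#' @param latent_grid side g of the g x g latent grid (default 48, i.e. a
#'   2304-dimensional posterior).
#' @param enc_channels widths of the four encoder convolutions.
#' @param dec_channels widths of the five decoder transposed convolutions.
#' @param beta KL weight; small, prioritizing reconstruction.
#' @return list of class `vae_config`.
#' @export
vae_config <- function(input_shape = c(200L, 794L), latent_grid = 48L,
                       enc_channels = c(16L, 32L, 64L, 64L),
                       dec_channels = c(64L, 64L, 32L, 16L, 8L),
                       beta = 1e-4) {
  stopifnot(length(enc_channels) == 4, length(dec_channels) == 5, beta >= 0)
  down <- function(n) (n - 1L) %/% 2L + 1L # k=3, p=1, s=2
  h <- input_shape[1]; w <- input_shape[2]
  w1 <- down(w); w2 <- down(w1)            # two stride-(1,2) layers
  h3 <- down(h); w3 <- down(w2)            # stride-(2,2)
  h4 <- down(h3); w4 <- down(w3)           # stride-(2,2)
  structure(list(input_shape = as.integer(input_shape),
                 latent_grid = as.integer(latent_grid),
                 enc_channels = as.integer(enc_channels),
                 dec_channels = as.integer(dec_channels),
                 pre_resize_shape = c(h4, w4),
                 beta = beta),
            class = "vae_config")
}

#' Initialize VAE weights
#'
#' Xavier-initialized convolution stacks with batch normalization, per the
#' architecture in [vae_config()].
#'
#' @param config a [vae_config()].
#' @param seed integer seed for the weight draws.
#' @return model object of class `vae_model`.
#' @export
vae_init <- function(config, seed = 1L) {
  set.seed(seed)
  ec <- config$enc_channels; dc <- config$dec_channels
  g <- config$latent_grid
  enc <- list(
    nn_conv(1, ec[1], stride = c(1L, 2L)), nn_batchnorm(ec[1]), nn_lrelu(),
    nn_conv(ec[1], ec[2], stride = c(1L, 2L)), nn_batchnorm(ec[2]), nn_lrelu(),
    nn_conv(ec[2], ec[3], stride = c(2L, 2L)), nn_batchnorm(ec[3]), nn_lrelu(),
    nn_conv(ec[3], ec[4], stride = c(2L, 2L)), nn_batchnorm(ec[4]), nn_lrelu(),
    nn_resize(g, g),
    nn_conv(ec[4], 2, k = c(1L, 1L), pad = c(0L, 0L))
  )
  enc[[1]]$need_dx <- FALSE # image gradient is never consumed
  pre <- config$pre_resize_shape
  dec <- list(
    nn_resize(pre[1], pre[2]),
    nn_conv(1, dc[1], k = c(1L, 1L), pad = c(0L, 0L)),
    nn_convt(dc[1], dc[2], k = c(4L, 4L), stride = c(2L, 2L)),
    nn_batchnorm(dc[2]), nn_lrelu(),
    nn_convt(dc[2], dc[3], k = c(4L, 4L), stride = c(2L, 2L)),
    nn_batchnorm(dc[3]), nn_lrelu(),
    nn_convt(dc[3], dc[4], k = c(3L, 4L), stride = c(1L, 2L)),
    nn_batchnorm(dc[4]), nn_lrelu(),
    nn_convt(dc[4], dc[5], k = c(3L, 4L), stride = c(1L, 2L)),
    nn_batchnorm(dc[5]), nn_lrelu(),
    nn_convt(dc[5], 1, k = c(3L, 3L), stride = c(1L, 1L)),
    nn_resize(config$input_shape[1], config$input_shape[2]),
    nn_tanh()
  )
  m <- new.env(parent = emptyenv())
  m$config <- config; m$enc <- enc; m$dec <- dec
  class(m) <- "vae_model"
  m
}

# images: list of H x W matrices, or (H, W, N) array, in [-1, 1]
images_to_array <- function(images) {
  if (is.list(images)) {
    d <- dim(images[[1]])
    x <- array(unlist(images, use.names = FALSE), c(d[1], d[2], 1, length(images)))
  } else if (length(dim(images)) == 3) {
    d <- dim(images)
    x <- array(images, c(d[1], d[2], 1, d[3]))
  } else if (length(dim(images)) == 4) {
    x <- images
  } else {
    d <- dim(images)
    x <- array(images, c(d[1], d[2], 1, 1))
  }
  x
}

#' Encode images to the latent posterior
#'
#' @param model a trained (or freshly initialized) `vae_model`.
#' @param images list of H x W matrices, or an (H, W, N) array, with values
#'   in `[-1, 1]`.
#' @param training internal flag: use batch statistics and keep caches.
#' @return list with `mu` and `logvar`, each a D x N matrix (D = g^2).
#' @export
vae_encode <- function(model, images, training = FALSE) {
  x <- images_to_array(images)
  d <- dim(x)
  if (!all(d[1:2] == model$config$input_shape)) {
    stop("shape mismatch: expected ", paste(model$config$input_shape, collapse = "x"),
         " input, got ", d[1], "x", d[2])
  }
  h <- nn_sequential_fwd(model$enc, x, training)
  g <- model$config$latent_grid
  mu <- matrix(h[, , 1, ], g * g, d[4])
  logvar <- matrix(h[, , 2, ], g * g, d[4])
  model$logvar_clip <- abs(logvar) > LOGVAR_CLAMP # gradient mask for training
  logvar <- pmin(pmax(logvar, -LOGVAR_CLAMP), LOGVAR_CLAMP)
  list(mu = mu, logvar = logvar)
}

#' Reparameterization trick
#'
#' `z = mu + exp(0.5 * logvar) * eps`, reshaped to the g x g latent grid.
#'
#' @param mu,logvar D-vectors or D x N matrices (D = g^2).
#' @param eps standard-normal draw of the same shape; drawn internally when
#'   NULL.
#' @return for vector input a g x g matrix; for matrix input a
#'   (g, g, 1, N) array. The draw used is attached as attribute `eps`.
#' @export
vae_reparameterize <- function(mu, logvar, eps = NULL) {
  if (!is.null(dim(mu)) && !all(dim(mu) == dim(logvar)) ||
      length(mu) != length(logvar)) {
    stop("length mismatch between mu and logvar")
  }
  if (is.null(eps)) eps <- array(stats::rnorm(length(mu)), dim = dim(mu) %||% length(mu))
  if (length(eps) != length(mu)) stop("length mismatch between mu and eps")
  z <- mu + exp(0.5 * logvar) * eps
  g <- as.integer(round(sqrt(if (is.matrix(mu)) nrow(mu) else length(mu))))
  if (g * g != (if (is.matrix(mu)) nrow(mu) else length(mu))) {
    stop("latent dimension is not a perfect square")
  }
  z <- if (is.matrix(mu)) array(z, c(g, g, 1, ncol(mu))) else matrix(z, g, g)
  attr(z, "eps") <- eps
  z
}

#' Decode latents back to image space
#'
#' @param model a `vae_model`.
#' @param z g x g matrix, (g, g, 1, N) array or D x N matrix of latents.
#' @param training internal flag.
#' @return (H, W, 1, N) array with values in `[-1, 1]`.
#' @export
vae_decode <- function(model, z, training = FALSE) {
  g <- model$config$latent_grid
  if (is.matrix(z) && nrow(z) == g && ncol(z) == g) z <- array(z, c(g, g, 1, 1))
  if (is.matrix(z) && nrow(z) == g * g) z <- array(z, c(g, g, 1, ncol(z)))
  if (!all(dim(z)[1:2] == c(g, g))) stop("latent shape mismatch: expected ", g, "x", g)
  nn_sequential_fwd(model$dec, z, training)
}

#' VAE training loss
#'
#' Mean over the batch of per-pixel-mean squared reconstruction error plus
#' `beta` times the closed-form KL divergence of the diagonal-Gaussian
#' posterior from N(0, I) (summed over latent dimensions).
#'
#' @param x,xhat original and reconstructed image arrays of equal shape.
#' @param mu,logvar posterior parameters, D x N.
#' @param beta KL weight, nonnegative.
#' @return scalar loss.
#' @export
vae_loss <- function(x, xhat, mu, logvar, beta = 1e-4) {
  if (beta < 0) stop("beta must be nonnegative")
  x <- images_to_array(x); xhat <- images_to_array(xhat)
  stopifnot(all(dim(x) == dim(xhat)))
  n <- dim(x)[4]
  npix <- prod(dim(x)[1:3])
  mu <- as.matrix(mu); logvar <- as.matrix(logvar)
  mse <- sum((x - xhat)^2) / (npix * n)
  kl <- sum(-0.5 * (1 + logvar - mu^2 - exp(logvar))) / n
  mse + beta * kl
}

#' Train the VAE
#'
#' Adam on the [vae_loss()], with a stratification-free random train/val
#' split, early stopping on the best validation loss, and best-epoch
#' checkpointing.
#'
#' @param images list of H x W matrices or (H, W, N) array in `[-1, 1]`.
#' @param config a [vae_config()].
#' @param epochs maximum epochs.
#' @param lr Adam learning rate (default 1e-4).
#' @param batch_size minibatch size.
#' @param val_fraction fraction held out for validation (ignored when
#'   `val_ids` given).
#' @param val_ids optional explicit validation indices.
#' @param patience early-stopping patience in epochs.
#' @param seed integer seed (weights, split, shuffling, eps draws).
#' @param verbose print per-epoch losses.
#' @return list with `model` (best-validation weights) and `report`
#'   (data.frame epoch/train_loss/val_loss plus `best_epoch`,
#'   `early_stopped` attributes).
#' @export
fit_vae <- function(images, config, epochs = 200L, lr = 1e-4, batch_size = 32L,
                    val_fraction = 0.2, val_ids = NULL, patience = 10L,
                    seed = 1L, verbose = FALSE) {
  x_all <- images_to_array(images)
  n <- dim(x_all)[4]
  stopifnot(n >= 2)
  model <- vae_init(config, seed = seed)
  set.seed(seed + 1L)
  if (is.null(val_ids)) {
    n_val <- max(1L, round(val_fraction * n))
    val_ids <- sort(sample(n, n_val))
  }
  tr_ids <- setdiff(seq_len(n), val_ids)
  beta <- config$beta
  g <- config$latent_grid; D <- g * g
  npix <- prod(dim(x_all)[1:3])
  report <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
  best_val <- Inf; best_state <- NULL; best_epoch <- 0L; bad <- 0L
  early <- FALSE

  for (ep in seq_len(epochs)) {
    ord <- sample(tr_ids)
    tr_loss <- 0; nb <- 0L
    for (b0 in seq(1, length(ord), by = batch_size)) {
      ids <- ord[b0:min(b0 + batch_size - 1, length(ord))]
      xb <- x_all[, , , ids, drop = FALSE]
      nbatch <- length(ids)
      post <- vae_encode(model, xb, training = TRUE)
      z <- vae_reparameterize(post$mu, post$logvar)
      eps <- attr(z, "eps")
      xhat <- vae_decode(model, z, training = TRUE)
      loss <- vae_loss(xb, xhat, post$mu, post$logvar, beta)
      if (!is.finite(loss)) stop("NaN/Inf VAE loss at epoch ", ep,
                                 "; try a lower learning rate")
      tr_loss <- tr_loss + loss; nb <- nb + 1L
      nn_zero_all(list(model$enc, model$dec))
      dxhat <- 2 * (xhat - xb) / (npix * nbatch)
      dz <- nn_sequential_bwd(model$dec, dxhat)
      dz_mat <- matrix(dz, D, nbatch)
      sig <- exp(0.5 * post$logvar)
      dmu <- dz_mat + beta * post$mu / nbatch
      dlv <- dz_mat * eps * 0.5 * sig + beta * 0.5 * (exp(post$logvar) - 1) / nbatch
      dlv[model$logvar_clip] <- 0
      gh <- array(0, c(g, g, 2, nbatch))
      gh[, , 1, ] <- dmu
      gh[, , 2, ] <- dlv
      nn_sequential_bwd(model$enc, gh)
      nn_adam_step(list(model$enc, model$dec), lr)
    }
    # validation (eval mode, deterministic: z = mu)
    postv <- vae_encode(model, x_all[, , , val_ids, drop = FALSE], training = FALSE)
    xhatv <- vae_decode(model, array(postv$mu, c(g, g, 1, length(val_ids))),
                        training = FALSE)
    val_loss <- vae_loss(x_all[, , , val_ids, drop = FALSE], xhatv,
                         postv$mu, postv$logvar, beta)
    report <- rbind(report, data.frame(epoch = ep, train_loss = tr_loss / nb,
                                       val_loss = val_loss))
    if (verbose) message(sprintf("epoch %d train %.5f val %.5f", ep,
                                 tr_loss / nb, val_loss))
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss; best_epoch <- ep; bad <- 0L
      best_state <- rapply(nn_get_state(list(model$enc, model$dec)),
                           identity, how = "replace")
    } else {
      bad <- bad + 1L
      if (bad >= patience) { early <- TRUE; break }
    }
  }
  if (!is.null(best_state)) nn_set_state(list(model$enc, model$dec), best_state)
  attr(report, "best_epoch") <- best_epoch
  attr(report, "early_stopped") <- early
  list(model = model, report = report)
}
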