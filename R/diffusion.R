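# Conditional latent diffusion: linear forward-noising schedule, the
# noise-prediction training objective, and the ancestral reverse step with
# fixed variance r_t * I.

#' Linear forward-noising schedule
#'
#' Per-step noise variances r_t are linearly interpolated between
#' `r_start` and `r_end` over t = 1..T (endpoints included); retentions
#' a_t = 1 - r_t and cumulative products alpha_bar_t = prod_{s<=t} a_s are
#' derived. alpha_bar_0 is defined as 1.
#'
#' @param T step count (default 350).
#' @param r_start,r_end endpoints of the noise-variance ramp.
#' @return list of class `noise_schedule` with fields `T`, `r`, `a`, `abar`.
#' @export
make_linear_schedule <- function(T = 350L, r_start = 1e-4, r_end = 0.02) {
  if (!(r_start > 0 && r_start < r_end && r_end < 1)) {
    stop("schedule endpoints must satisfy 0 < r_start < r_end < 1")
  }
  stopifnot(T >= 1)
  r <- if (T == 1) r_start else seq(r_start, r_end, length.out = T)
  a <- 1 - r
  structure(list(T = as.integer(T), r = r, a = a, abar = cumprod(a)),
            class = "noise_schedule")
}

#' Forward-noise a latent to step t
#'
#' `z_t = sqrt(abar_t) * z0 + sqrt(1 - abar_t) * eps`, elementwise. With
#' unit-variance z0 the marginal variance is preserved at every t.
#'
#' @param z0 latent (any shape; vector, g x g matrix, D x N matrix or array).
#' @param t integer step in 1..T; scalar, or length N for column-wise steps
#'   on a D x N matrix.
#' @param eps standard-normal noise of the same shape (drawn when NULL).
#' @param schedule a [make_linear_schedule()].
#' @return noised latent of the same shape, with attribute `eps`.
#' @export
forward_noise <- function(z0, t, eps = NULL, schedule) {
  if (any(t < 1) || any(t > schedule$T)) stop("t out of range 1..", schedule$T)
  if (is.null(eps)) eps <- array(stats::rnorm(length(z0)), dim = dim(z0) %||% length(z0))
  stopifnot(length(eps) == length(z0))
  ab <- schedule$abar[t]
  if (length(t) > 1) { # column-wise steps for D x N matrices
    stopifnot(is.matrix(z0), ncol(z0) == length(t))
    zt <- sweep(z0, 2, sqrt(ab), "*") + sweep(eps, 2, sqrt(1 - ab), "*")
  } else {
    zt <- sqrt(ab) * z0 + sqrt(1 - ab) * eps
  }
  attr(zt, "eps") <- eps
  zt
}

#' Noise-prediction training loss
#'
#' Elementwise mean squared error between the true noise and
#' eps_theta(z_t, t, c), averaged over the batch, with t sampled uniformly
#' on 1..T per example when not supplied.
#'
#' @param model a `denoiser_model`.
#' @param z0 latents, D x N matrix (D = g^2).
#' @param cond condition index list (`genotype`, `clutch`, `age`).
#' @param schedule a [make_linear_schedule()].
#' @param t,eps optional fixed steps / noise (for tests).
#' @return scalar loss.
#' @export
ldm_loss <- function(model, z0, cond, schedule, t = NULL, eps = NULL) {
  n <- ncol(z0)
  if (is.null(t)) t <- sample.int(schedule$T, n, replace = TRUE)
  zt <- forward_noise(z0, t, eps, schedule)
  eps <- attr(zt, "eps")
  eps_hat <- denoiser_predict(model, zt, t, cond)
  mean((eps - eps_hat)^2)
}

#' One reverse (denoising) step
#'
#' Samples z_{t-1} from N(mu_theta, r_t I) where mu_theta is the standard
#' noise-prediction posterior mean
#' `(z_t - r_t / sqrt(1 - abar_t) * eps_theta) / sqrt(a_t)`;
#' at t = 1 the mean is returned without added noise.
#'
#' @param z_t latent at step t (g x g matrix, (g,g,1,N) array or D x N).
#' @param t integer step in 1..T.
#' @param cond condition index list.
#' @param model a `denoiser_model`, or a function `(z_t, t, cond) -> eps_hat`
#'   (an explicit noise predictor, e.g. an exact oracle in tests).
#' @param schedule a [make_linear_schedule()].
#' @param noise optional standard-normal draw (same shape as `z_t`).
#' @return z_{t-1}, same shape as the input.
#' @export
denoise_step <- function(z_t, t, cond, model, schedule, noise = NULL) {
  if (t < 1 || t > schedule$T) stop("t out of range 1..", schedule$T)
  eps_hat <- if (is.function(model)) model(z_t, t, cond) else
    denoiser_predict(model, z_t, t, cond)
  rt <- schedule$r[t]; at <- schedule$a[t]; ab <- schedule$abar[t]
  mu <- (z_t - rt / sqrt(1 - ab) * eps_hat) / sqrt(at)
  if (t == 1) return(mu)
  if (is.null(noise)) noise <- array(stats::rnorm(length(z_t)),
                                     dim = dim(z_t) %||% length(z_t))
  mu + sqrt(rt) * noise
}

# full reverse chain from step `from_t` down to 1
reverse_chain <- function(z, from_t, cond, model, schedule) {
  for (t in seq.int(from_t, 1L)) z <- denoise_step(z, t, cond, model, schedule)
  z
}

#' Train the conditional latent diffusion model
#'
#' Adam on the noise-prediction loss with uniformly sampled timesteps, a
#' fixed validation noising (so validation loss is deterministic), early
#' stopping on best validation loss and best-epoch checkpointing. Latents
#' are standardized (per-dimension shift, global scale) before diffusion;
#' the statistics are stored on the model and undone at correction time.
#'
#' @param latents D x N matrix of latent posteriors (typically VAE means).
#' @param cond condition index list aligned with the latent columns
#'   (integer vectors `genotype`, `clutch`, `age`).
#' @param config a [denoiser_config()].
#' @param schedule a [make_linear_schedule()].
#' @param epochs maximum epochs (paper-scale default 2000).
#' @param lr Adam learning rate (default 1e-4).
#' @param batch_size minibatch size.
#' @param val_fraction validation fraction (ignored when `val_ids` given).
#' @param val_ids optional explicit validation column indices.
#' @param patience early-stopping patience in epochs.
#' @param val_every evaluate the validation loss every this many epochs
#'   (1 = every epoch; larger values save time when early stopping is
#'   effectively disabled by a large patience).
#' @param lr_schedule `"constant"` or `"cosine"` (cosine decay to 10\% of
#'   `lr` over the epoch budget; useful for short training runs).
#' @param ema_decay exponential-moving-average decay for the weights used at
#'   sampling time (0 disables EMA). The raw best-validation weights drive
#'   early stopping; the returned model carries the EMA weights.
#' @param seed integer seed.
#' @param verbose print per-epoch losses.
#' @return list with `model` (best weights, plus `latent_shift`,
#'   `latent_scale`, `cond_levels` if supplied via attr) and `report`.
#' @export
fit_ldm <- function(latents, cond, config, schedule, epochs = 2000L, lr = 1e-4,
                    batch_size = 64L, val_fraction = 0.2, val_ids = NULL,
                    patience = 10L, val_every = 1L,
                    lr_schedule = c("constant", "cosine"),
                    ema_decay = 0.995, seed = 1L, verbose = FALSE) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(is.matrix(latents))
  D <- nrow(latents); n <- ncol(latents)
  g <- config$latent_grid
  stopifnot(D == g * g)
  model <- denoiser_init(config, seed = seed)
  model$latent_shift <- rowMeans(latents)
  centered <- latents - model$latent_shift
  # per-dimension standardization keeps weakly expressed factors visible to
  # the conditional model; floored so dead dimensions stay dead
  sds <- sqrt(rowMeans(centered^2))
  model$latent_scale <- pmax(sds, 0.05 * max(sds, 1e-8))
  if (inherits(cond, "condition_index")) model$cond_levels <- cond$levels
  z_all <- (latents - model$latent_shift) / model$latent_scale

  set.seed(seed + 1L)
  if (is.null(val_ids)) {
    val_ids <- sort(sample(n, max(1L, round(val_fraction * n))))
  }
  tr_ids <- setdiff(seq_len(n), val_ids)
  sub_cond <- function(ids) list(genotype = cond$genotype[ids],
                                 clutch = cond$clutch[ids],
                                 age = cond$age[ids])
  # fixed validation noising -> deterministic validation loss
  val_t <- sample.int(schedule$T, length(val_ids), replace = TRUE)
  val_eps <- matrix(stats::rnorm(D * length(val_ids)), D)
  val_cond <- sub_cond(val_ids)

  report <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
  best_val <- Inf; best_state <- NULL; best_epoch <- 0L; bad <- 0L
  early <- FALSE
  ema <- if (ema_decay > 0) nn_get_state(model$layer_groups) else NULL
  for (ep in seq_len(epochs)) {
    lr_ep <- if (lr_schedule == "cosine") {
      0.1 * lr + 0.45 * lr * (1 + cos(pi * (ep - 1) / max(epochs - 1, 1)))
    } else lr
    ord <- sample(tr_ids)
    tr_loss <- 0; nb <- 0L
    for (b0 in seq(1, length(ord), by = batch_size)) {
      ids <- ord[b0:min(b0 + batch_size - 1, length(ord))]
      nbatch <- length(ids)
      z0 <- z_all[, ids, drop = FALSE]
      tt <- sample.int(schedule$T, nbatch, replace = TRUE)
      eps <- matrix(stats::rnorm(D * nbatch), D)
      zt <- forward_noise(z0, tt, eps, schedule)
      zt_arr <- array(zt, c(g, g, 1, nbatch))
      eps_hat <- denoiser_fwd(model, zt_arr, tt, sub_cond(ids), training = TRUE)
      loss <- mean((matrix(eps_hat, D) - eps)^2)
      if (!is.finite(loss)) stop("NaN/Inf diffusion loss at epoch ", ep,
                                 "; try a lower learning rate")
      tr_loss <- tr_loss + loss; nb <- nb + 1L
      nn_zero_all(model$layer_groups)
      gout <- array(2 * (matrix(eps_hat, D) - eps) / (D * nbatch),
                    c(g, g, 1, nbatch))
      denoiser_bwd(model, gout)
      nn_adam_step(model$layer_groups, lr_ep)
      if (!is.null(ema)) ema <- nn_ema_update(model$layer_groups, ema, ema_decay)
    }
    if (ep %% val_every == 0 || ep == epochs) {
      val_loss <- ldm_loss(model, z_all[, val_ids, drop = FALSE], val_cond,
                           schedule, t = val_t, eps = val_eps)
      report <- rbind(report, data.frame(epoch = ep, train_loss = tr_loss / nb,
                                         val_loss = val_loss))
      if (verbose) message(sprintf("epoch %d train %.5f val %.5f", ep,
                                   tr_loss / nb, val_loss))
      if (val_loss < best_val - 1e-12) {
        best_val <- val_loss; best_epoch <- ep; bad <- 0L
        best_state <- nn_get_state(model$layer_groups)
      } else {
        bad <- bad + val_every
        if (bad >= patience) { early <- TRUE; break }
      }
    }
  }
  if (!is.null(ema)) {
    nn_set_state(model$layer_groups, ema)
  } else if (!is.null(best_state)) {
    nn_set_state(model$layer_groups, best_state)
  }
  attr(report, "best_epoch") <- best_epoch
  attr(report, "early_stopped") <- early
  list(model = model, report = report)
}
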