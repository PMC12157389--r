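# Diffusion machinery: schedule construction, forward-noising identities,
# reverse-step algebra against an exact oracle, and a small training run.

test_that("the linear schedule hits its endpoints and decays its cumulative product", {
  s <- make_linear_schedule(350L)
  expect_identical(s$T, 350L)
  expect_equal(s$r[1], 1e-4)
  expect_equal(s$r[350], 0.02)
  expect_true(all(diff(s$abar) < 0))
  expect_true(all(s$abar > 0 & s$abar <= 1))
  # brute-force product oracle, term by term
  prod_oracle <- 1
  for (t in 1:350) prod_oracle <- prod_oracle * (1 - s$r[t])
  expect_lt(abs(s$abar[350] - prod_oracle), 1e-12)
  expect_error(make_linear_schedule(100L, 0.02, 1e-4), "endpoints")
  expect_error(make_linear_schedule(100L, 0, 0.5), "endpoints")
})

test_that("forward noising follows its closed form and preserves marginal variance", {
  s <- make_linear_schedule(50L)
  z0 <- matrix(rnorm(36), 6, 6)
  zt <- forward_noise(z0, 20L, eps = array(0, dim(z0)), schedule = s)
  expect_equal(unclass(zt), sqrt(s$abar[20]) * z0, ignore_attr = TRUE)
  e <- matrix(rnorm(36), 6, 6)
  zt2 <- forward_noise(matrix(0, 6, 6), 20L, eps = e, schedule = s)
  expect_equal(unclass(zt2), sqrt(1 - s$abar[20]) * e, ignore_attr = TRUE)
  expect_error(forward_noise(z0, 51L, schedule = s), "out of range")
  # variance preservation for unit-variance z0, Monte-Carlo
  set.seed(10)
  n <- 10000
  for (t in c(1L, 25L, 50L)) {
    z <- rnorm(n)
    zt <- forward_noise(z, t, schedule = s)
    expect_lt(abs(var(as.vector(zt)) - 1), 0.05)
  }
})

test_that("an exact-noise oracle inverts one forward step", {
  s <- make_linear_schedule(100L)
  set.seed(4)
  z0 <- matrix(rnorm(64), 8, 8)
  eps <- matrix(rnorm(64), 8, 8)
  z1 <- forward_noise(z0, 1L, eps = eps, schedule = s)
  oracle <- function(z_t, t, cond) eps
  rec <- denoise_step(unclass(z1), 1L, NULL, oracle, s)
  expect_lt(max(abs(rec - z0)) / max(abs(z0)), 1e-5)
  expect_error(denoise_step(z1, 0L, NULL, oracle, s), "out of range")
})

test_that("a full reverse pass with a null-noise oracle stays finite", {
  s <- make_linear_schedule(100L)
  set.seed(5)
  z <- matrix(rnorm(64), 8, 8)
  oracle0 <- function(z_t, t, cond) array(0, dim(z_t))
  out <- clutchcorrect:::reverse_chain(z, 100L, NULL, oracle0, s)
  expect_true(all(is.finite(out)))
  # magnitudes grow by the 1/sqrt(a_t) cascade (plus injected reverse noise)
  ratio <- mean(abs(out)) / mean(abs(z))
  expect_gt(ratio, prod(1 / sqrt(s$a)) * 0.8)
  expect_lt(ratio, prod(1 / sqrt(s$a)) * 4)
  # seeded determinism of the stochastic reverse step
  dn <- denoiser_init(denoiser_config(8L, 4L, 8L, 2L, 2L, 1L, groups = 2L), seed = 2)
  cond <- list(genotype = 1L, clutch = 1L, age = 1L)
  set.seed(7); a <- denoise_step(z, 50L, cond, dn, s)
  set.seed(7); b <- denoise_step(z, 50L, cond, dn, s)
  expect_identical(a, b)
})

test_that("a freshly initialized denoiser predicts zero, so the loss is E||eps||^2/D", {
  cfg <- denoiser_config(8L, 4L, 8L, 2L, 2L, 1L, groups = 2L)
  m <- denoiser_init(cfg, seed = 3)
  s <- make_linear_schedule(50L)
  set.seed(6)
  z0 <- matrix(rnorm(64 * 40), 64)
  cond <- list(genotype = rep(1:2, 20), clutch = rep(1:2, each = 20),
               age = rep(1L, 40))
  # the output convolution starts at zero, so eps_hat = 0 exactly
  pred <- denoiser_predict(m, z0, 10L, cond)
  expect_true(all(pred == 0))
  loss <- ldm_loss(m, z0, cond, s)
  expect_lt(abs(loss - 1), 0.1) # mean of 2560 chi-square_1 draws
})

test_that("swapping the condition embedding steers denoising toward the target", {
  set.seed(9)
  D <- 64
  n <- 80
  half <- n / 2
  lat <- cbind(matrix(rnorm(D * half, mean = 2), D),
               matrix(rnorm(D * half, mean = -2), D))
  ci <- structure(list(genotype = rep(c(1L, 2L), each = half),
                       clutch = rep(1L, n), age = rep(1L, n),
                       levels = list(genotype = c("a", "b"), clutch = "x",
                                     age = "y")),
                  class = "condition_index")
  # deep terminal noising so the condition cannot be read off z_T itself
  s <- make_linear_schedule(40L, r_end = 0.3)
  cfg <- denoiser_config(8L, 4L, 16L, 2L, 1L, 1L, groups = 2L)
  fit <- fit_ldm(lat, ci, cfg, s, epochs = 80, lr = 3e-3, batch_size = 40,
                 patience = 80, lr_schedule = "cosine", seed = 1)
  rep <- fit$report
  expect_lt(tail(rep$val_loss, 1), rep$val_loss[1])
  expect_lte(nrow(rep), attr(rep, "best_epoch") + 80)
  # forward-noise condition-1 latents, then denoise under each condition:
  # the swapped embedding must pull the output toward the condition-2 mean
  zs <- (lat - fit$model$latent_shift) / fit$model$latent_scale
  za <- zs[, 1:20]
  set.seed(33)
  zt <- forward_noise(za, 40L, NULL, s)
  attr(zt, "eps") <- NULL
  den <- function(code) {
    cond <- list(genotype = rep(code, 20), clutch = rep(1L, 20), age = rep(1L, 20))
    set.seed(44)
    out <- clutchcorrect:::reverse_chain(array(zt, c(8, 8, 1, 20)), 40L, cond,
                                         fit$model, s)
    mean(out * fit$model$latent_scale + fit$model$latent_shift)
  }
  expect_gt(den(1L) - den(2L), 0.1)
})
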