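# Conditional U-Net noise predictor eps_theta(z_t, t, c) on the latent grid:
# one downsampling and one upsampling level with residual blocks, group
# normalization, SiLU activations, a sinusoidal timestep embedding passed
# through a small MLP, and additive learned embeddings for the three
# condition factors (genotype / clutch / age), injected into every residual
# block through a per-block linear projection.

# broadcast a (C, N) matrix over the spatial dims of an (H, W, C, N) array
emb_broadcast_add <- function(x, v) {
  d <- dim(x)
  y <- x + cc_block_expand(as.vector(v), d[1] * d[2])
  dim(y) <- d
  y
}

# adjoint of the broadcast: sum an (H, W, C, N) gradient over H, W -> (C, N)
emb_spatial_sum <- function(g) {
  d <- dim(g)
  matrix(cc_block_sum2(g, d[1] * d[2])$sum, d[3], d[4])
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Residual block with embedding injection; returns env with fwd/bwd.
unet_resblock <- function(cin, cout, emb_dim, groups) {
  rb <- new.env(parent = emptyenv())
  rb$gn1 <- nn_groupnorm(cin, min(groups, cin))
  rb$act1 <- nn_silu()
  rb$conv1 <- nn_conv(cin, cout)
  rb$proj <- nn_dense(emb_dim, cout)
  rb$gn2 <- nn_groupnorm(cout, min(groups, cout))
  rb$act2 <- nn_silu()
  rb$conv2 <- nn_conv(cout, cout)
  rb$skip <- if (cin != cout) nn_conv(cin, cout, k = c(1L, 1L), pad = c(0L, 0L)) else NULL
  rb$layers <- Filter(Negate(is.null),
                      list(rb$gn1, rb$act1, rb$conv1, rb$proj, rb$gn2, rb$act2,
                           rb$conv2, rb$skip))
  rb$fwd <- function(x, emb, training = TRUE) {
    h <- rb$conv1$fwd(rb$act1$fwd(rb$gn1$fwd(x, training)), training)
    h <- emb_broadcast_add(h, rb$proj$fwd(emb, training))
    h2 <- rb$conv2$fwd(rb$act2$fwd(rb$gn2$fwd(h, training)), training)
    s <- if (is.null(rb$skip)) x else rb$skip$fwd(x, training)
    h2 + s
  }
  rb$bwd <- function(gy) {
    gs <- if (is.null(rb$skip)) gy else rb$skip$bwd(gy)
    gh <- rb$gn2$bwd(rb$act2$bwd(rb$conv2$bwd(gy)))
    g_emb <- rb$proj$bwd(emb_spatial_sum(gh))
    gx <- rb$gn1$bwd(rb$act1$bwd(rb$conv1$bwd(gh)))
    list(gx = gx + gs, g_emb = g_emb)
  }
  rb
}

sinusoidal_embedding <- function(t, emb_dim) {
  half <- emb_dim %/% 2
  freqs <- exp(-log(10000) * (seq_len(half) - 1) / max(half - 1, 1))
  ang <- outer(freqs, as.numeric(t)) # (half, N)
  rbind(sin(ang), cos(ang))
}

#' Denoiser (conditional U-Net) configuration
#'
#' @param latent_grid side g of the latent grid (must be even).
#' @param base_channels channel width at full resolution (doubled after the
#'   downsampling step).
#' @param emb_dim dimension of the timestep/condition embeddings.
#' @param n_genotype,n_clutch,n_age numbers of condition codes.
#' @param groups group-normalization group count.
#' @return list of class `denoiser_config`.
#' @export
denoiser_config <- function(latent_grid = 16L, base_channels = 16L,
                            emb_dim = 32L, n_genotype, n_clutch, n_age,
                            groups = 4L) {
  stopifnot(latent_grid %% 2 == 0, emb_dim %% 2 == 0,
            n_genotype >= 1, n_clutch >= 1, n_age >= 1)
  structure(list(latent_grid = as.integer(latent_grid),
                 base_channels = as.integer(base_channels),
                 emb_dim = as.integer(emb_dim),
                 n_genotype = as.integer(n_genotype),
                 n_clutch = as.integer(n_clutch),
                 n_age = as.integer(n_age),
                 groups = as.integer(groups)),
            class = "denoiser_config")
}

#' Initialize the conditional U-Net denoiser
#'
#' @param config a [denoiser_config()].
#' @param seed integer seed.
#' @return model object of class `denoiser_model`.
#' @export
denoiser_init <- function(config, seed = 1L) {
  set.seed(seed)
  C <- config$base_channels; E <- config$emb_dim; G <- config$groups
  m <- new.env(parent = emptyenv())
  m$config <- config
  m$conv_in <- nn_conv(1, C)
  m$rb1 <- unet_resblock(C, C, E, G)
  m$down <- nn_conv(C, 2 * C, stride = c(2L, 2L))
  m$rb2 <- unet_resblock(2 * C, 2 * C, E, G)
  m$mid <- unet_resblock(2 * C, 2 * C, E, G)
  m$up <- nn_convt(2 * C, C, k = c(4L, 4L), stride = c(2L, 2L))
  m$rb3 <- unet_resblock(2 * C, C, E, G)
  m$out_gn <- nn_groupnorm(C, min(G, C))
  m$out_act <- nn_silu()
  m$out_conv <- nn_conv(C, 1)
  m$t_d1 <- nn_dense(E, E)
  m$t_act <- nn_silu()
  m$t_d2 <- nn_dense(E, E)
  m$stem_proj <- nn_dense(E, C) # condition injection at the stem
  m$emb_genotype <- nn_embedding(config$n_genotype, E)
  m$emb_clutch <- nn_embedding(config$n_clutch, E)
  m$emb_age <- nn_embedding(config$n_age, E)
  # condition tables see only a fraction of the batches that touch the
  # shared trunk; a higher learning rate keeps them from lagging
  m$emb_genotype$lr_mult <- 3
  m$emb_clutch$lr_mult <- 3
  m$emb_age$lr_mult <- 3
  # start the output convolution at zero so the initial prediction is null
  m$out_conv$params$w[] <- 0
  m$layer_groups <- list(m$conv_in, m$rb1$layers, m$down, m$rb2$layers,
                         m$mid$layers, m$up, m$rb3$layers, m$out_gn,
                         m$out_act, m$out_conv, m$t_d1, m$t_act, m$t_d2,
                         m$stem_proj, m$emb_genotype, m$emb_clutch, m$emb_age)
  class(m) <- "denoiser_model"
  m
}

# cond: list with integer vectors genotype, clutch, age (length N or 1)
denoiser_fwd <- function(m, z, t, cond, training = TRUE) {
  d <- dim(z); n <- d[4]
  rep_n <- function(v) if (length(v) == 1) rep(v, n) else v
  t <- rep_n(t)
  gi <- rep_n(cond$genotype); ci <- rep_n(cond$clutch); ai <- rep_n(cond$age)
  temb <- m$t_d2$fwd(m$t_act$fwd(m$t_d1$fwd(
    sinusoidal_embedding(t, m$config$emb_dim), training), training), training)
  emb <- temb + m$emb_genotype$fwd(gi) + m$emb_clutch$fwd(ci) + m$emb_age$fwd(ai)
  m$cache_C <- m$config$base_channels
  x1 <- emb_broadcast_add(m$conv_in$fwd(z, training),
                          m$stem_proj$fwd(emb, training))
  r1 <- m$rb1$fwd(x1, emb, training)
  dn <- m$down$fwd(r1, training)
  r2 <- m$rb2$fwd(dn, emb, training)
  md <- m$mid$fwd(r2, emb, training)
  u <- m$up$fwd(md, training)
  r3 <- m$rb3$fwd(concat_channels(u, r1), emb, training)
  m$out_conv$fwd(m$out_act$fwd(m$out_gn$fwd(r3, training), training), training)
}

denoiser_bwd <- function(m, gout) {
  C <- m$cache_C
  g3 <- m$out_gn$bwd(m$out_act$bwd(m$out_conv$bwd(gout)))
  b3 <- m$rb3$bwd(g3)
  dcat <- b3$gx
  gu <- dcat[, , seq_len(C), , drop = FALSE]
  gr1a <- dcat[, , C + seq_len(C), , drop = FALSE]
  gmd <- m$up$bwd(gu)
  bm <- m$mid$bwd(gmd)
  b2 <- m$rb2$bwd(bm$gx)
  gr1b <- m$down$bwd(b2$gx)
  b1 <- m$rb1$bwd(gr1a + gr1b)
  gz <- m$conv_in$bwd(b1$gx)
  g_stem <- m$stem_proj$bwd(emb_spatial_sum(b1$gx))
  g_emb <- g_stem + b1$g_emb + b2$g_emb + bm$g_emb + b3$g_emb
  m$t_d1$bwd(m$t_act$bwd(m$t_d2$bwd(g_emb)))
  m$emb_genotype$bwd(g_emb)
  m$emb_clutch$bwd(g_emb)
  m$emb_age$bwd(g_emb)
  gz
}

#' Predict noise with the denoiser
#'
#' @param model a `denoiser_model`.
#' @param z_t latent array (g, g, 1, N) or D x N matrix.
#' @param t integer timestep(s), scalar or length N.
#' @param cond list of integer index vectors `genotype`, `clutch`, `age`
#'   (e.g. from the internal condition index of a coded table).
#' @param training internal flag.
#' @return predicted noise, same shape as `z_t`.
#' @export
denoiser_predict <- function(model, z_t, t, cond, training = FALSE) {
  g <- model$config$latent_grid
  was_flat <- is.matrix(z_t) && nrow(z_t) == g * g
  was_grid <- is.matrix(z_t) && all(dim(z_t) == c(g, g)) && !was_flat
  if (was_flat) z_t <- array(z_t, c(g, g, 1, ncol(z_t)))
  if (was_grid) z_t <- array(z_t, c(g, g, 1, 1))
  stopifnot(all(dim(z_t)[1:2] == c(g, g)))
  out <- denoiser_fwd(model, z_t, t, cond, training)
  if (was_flat) out <- matrix(out, g * g, dim(out)[4])
  if (was_grid) out <- matrix(out, g, g)
  out
}
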