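# Minimal neural-network layer toolkit used by the VAE, the diffusion U-Net
# and the classifier. Layers are environments carrying params/grads and
# fwd/bwd closures; activations are (H, W, C, N) arrays, dense activations are
# (D, N) matrices. Gradients are checked against finite differences in the
# test suite.

nn_layer <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  e$adam_m <- NULL
  e$adam_v <- NULL
  class(e) <- "nn_layer"
  e
}

# Xavier/Glorot uniform draw
nn_xavier <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

nn_zero_grads <- function(layer) {
  if (length(layer$grads) == length(layer$params) && length(layer$grads) > 0) {
    for (g in layer$grads) cc_fill0(g) # reuse buffers: zero in place
  } else {
    layer$grads <- lapply(layer$params, function(p) {
      if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p))
    })
  }
  invisible(layer)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-precision compute path for the convolution kernels (training
# default); exact double precision is used when the option is FALSE,
# e.g. in finite-difference gradient verification
nn_use_float <- function() {
  isTRUE(getOption("clutchcorrect.float", TRUE))
}

## ---- convolution ------------------------------------------------------

nn_conv <- function(cin, cout, k = c(3L, 3L), stride = c(1L, 1L), pad = c(1L, 1L)) {
  l <- nn_layer("conv")
  l$k <- as.integer(k); l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  fi <- k[1] * k[2] * cin; fo <- k[1] * k[2] * cout
  l$params <- list(w = nn_xavier(c(k[1], k[2], cin, cout), fi, fo),
                   b = rep(0, cout))
  nn_zero_grads(l)
  l$fwd <- function(x, training = TRUE) {
    l$x <- x
    cc_conv_fwd(x, dim(x), l$params$w, dim(l$params$w), l$params$b, l$stride,
                l$pad, nn_use_float())
  }
  l$need_dx <- TRUE # first layers of a stack can skip the input gradient
  l$bwd <- function(gy) {
    g <- cc_conv_bwd(l$x, dim(l$x), l$params$w, dim(l$params$w), gy, l$stride,
                     l$pad, l$need_dx, nn_use_float())
    cc_inplace_add(l$grads$w, g$dw)
    cc_inplace_add(l$grads$b, g$db)
    g$dx
  }
  l
}

nn_convt <- function(cin, cout, k = c(4L, 4L), stride = c(2L, 2L), pad = c(1L, 1L)) {
  l <- nn_layer("convt")
  l$k <- as.integer(k); l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  fi <- k[1] * k[2] * cin; fo <- k[1] * k[2] * cout
  # weight layout (kh, kw, cout, cin)
  l$params <- list(w = nn_xavier(c(k[1], k[2], cout, cin), fi, fo),
                   b = rep(0, cout))
  nn_zero_grads(l)
  l$fwd <- function(x, training = TRUE) {
    l$x <- x
    cc_convt_fwd(x, dim(x), l$params$w, dim(l$params$w), l$params$b, l$stride,
                 l$pad, nn_use_float())
  }
  l$need_dx <- TRUE
  l$bwd <- function(gy) {
    g <- cc_convt_bwd(l$x, dim(l$x), l$params$w, dim(l$params$w), gy, l$stride,
                      l$pad, l$need_dx, nn_use_float())
    cc_inplace_add(l$grads$w, g$dw)
    cc_inplace_add(l$grads$b, g$db)
    g$dx
  }
  l
}

## ---- normalization ----------------------------------------------------

# Batch normalization over (H, W, N) per channel, with running stats for eval.
nn_batchnorm <- function(c, momentum = 0.1, eps = 1e-5) {
  l <- nn_layer("batchnorm")
  l$eps <- eps; l$momentum <- momentum; l$c <- as.integer(c)
  l$params <- list(gamma = rep(1, c), beta = rep(0, c))
  l$running_mean <- rep(0, c); l$running_var <- rep(1, c)
  nn_zero_grads(l)
  l$fwd <- function(x, training = TRUE) {
    d <- dim(x); hw <- d[1] * d[2]; nn <- d[4]; m <- hw * nn
    if (training) {
      bs <- cc_block_sum2(x, hw)
      s1 <- rowSums(matrix(bs$sum, d[3], nn))
      s2 <- rowSums(matrix(bs$sumsq, d[3], nn))
      mu <- s1 / m
      va <- s2 / m - mu^2
      l$running_mean <- (1 - l$momentum) * l$running_mean + l$momentum * mu
      l$running_var <- (1 - l$momentum) * l$running_var + l$momentum * va
    } else {
      mu <- l$running_mean; va <- l$running_var
    }
    inv <- 1 / sqrt(va + l$eps)
    xhat <- cc_block_affine(x, hw, rep(inv, nn), rep(-mu * inv, nn))
    dim(xhat) <- d
    l$xhat <- xhat; l$inv <- inv; l$m <- m; l$training <- training
    y <- cc_block_affine(xhat, hw, rep(l$params$gamma, nn), rep(l$params$beta, nn))
    dim(y) <- d
    y
  }
  l$bwd <- function(gy) {
    d <- dim(gy); hw <- d[1] * d[2]; nn <- d[4]; m <- l$m
    dgam <- rowSums(matrix(cc_block_dot(gy, l$xhat, hw), d[3], nn))
    dbet <- rowSums(matrix(cc_block_sum2(gy, hw)$sum, d[3], nn))
    l$grads$gamma <- l$grads$gamma + dgam
    l$grads$beta <- l$grads$beta + dbet
    gam <- l$params$gamma
    if (!isTRUE(l$training)) {
      dx <- cc_block_affine(gy, hw, rep(gam * l$inv, nn), rep(0, d[3] * nn))
      dim(dx) <- d
      return(dx)
    }
    # s1 = per-channel sum of dxhat = gamma * dbeta; s2 = gamma * dgamma
    dx <- cc_block_affine(gy, hw, rep(gam * l$inv, nn), rep(0, d[3] * nn)) +
      cc_block_affine(l$xhat, hw, rep(-l$inv * gam * dgam / m, nn),
                      rep(-l$inv * gam * dbet / m, nn))
    dim(dx) <- d
    dx
  }
  l
}

# Group normalization over (H, W, C/G) per (group, sample).
nn_groupnorm <- function(c, groups = min(8L, c), eps = 1e-5) {
  stopifnot(c %% groups == 0)
  l <- nn_layer("groupnorm")
  l$eps <- eps; l$groups <- as.integer(groups); l$c <- as.integer(c)
  l$params <- list(gamma = rep(1, c), beta = rep(0, c))
  nn_zero_grads(l)
  l$fwd <- function(x, training = TRUE) {
    d <- dim(x); hw <- d[1] * d[2]; nn <- d[4]
    m <- hw * d[3] / l$groups
    bs <- cc_block_sum2(x, m)
    mu <- bs$sum / m
    va <- bs$sumsq / m - mu^2
    inv <- 1 / sqrt(va + l$eps)
    xhat <- cc_block_affine(x, m, inv, -mu * inv)
    dim(xhat) <- d
    l$xhat <- xhat; l$inv <- inv; l$m <- m; l$d <- d
    y <- cc_block_affine(xhat, hw, rep(l$params$gamma, nn), rep(l$params$beta, nn))
    dim(y) <- d
    y
  }
  l$bwd <- function(gy) {
    d <- l$d; hw <- d[1] * d[2]; nn <- d[4]; m <- l$m
    l$grads$gamma <- l$grads$gamma +
      rowSums(matrix(cc_block_dot(gy, l$xhat, hw), d[3], nn))
    l$grads$beta <- l$grads$beta +
      rowSums(matrix(cc_block_sum2(gy, hw)$sum, d[3], nn))
    dxhat <- cc_block_affine(gy, hw, rep(l$params$gamma, nn), rep(0, d[3] * nn))
    s1 <- cc_block_sum2(dxhat, m)$sum / m
    s2 <- cc_block_dot(dxhat, l$xhat, m) / m
    dx <- cc_block_affine(dxhat, m, l$inv, numeric(length(l$inv))) +
      cc_block_affine(l$xhat, m, -l$inv * s2, -l$inv * s1)
    dim(dx) <- d
    dx
  }
  l
}

## ---- activations ------------------------------------------------------

nn_lrelu <- function(slope = 0.2) {
  l <- nn_layer("lrelu"); l$slope <- slope
  l$fwd <- function(x, training = TRUE) {
    l$x <- x
    cc_lrelu_fwd(x, l$slope)
  }
  l$bwd <- function(gy) cc_lrelu_bwd(l$x, gy, l$slope)
  l
}

nn_silu <- function() {
  l <- nn_layer("silu")
  l$fwd <- function(x, training = TRUE) {
    s <- 1 / (1 + exp(-x))
    l$x <- x; l$s <- s
    x * s
  }
  l$bwd <- function(gy) gy * (l$s * (1 + l$x * (1 - l$s)))
  l
}

nn_tanh <- function() {
  l <- nn_layer("tanh")
  l$fwd <- function(x, training = TRUE) { l$y <- tanh(x); l$y }
  l$bwd <- function(gy) gy * (1 - l$y^2)
  l
}

## ---- bilinear resize --------------------------------------------------

# Interpolation matrix mapping `n_in` samples onto `n_out` (half-pixel centers)
nn_interp_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  if (n_in == 1) { A[, 1] <- 1; return(A) }
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * n_in / n_out - 0.5
    src <- min(max(src, 0), n_in - 1)
    lo <- floor(src); hi <- min(lo + 1, n_in - 1); f <- src - lo
    A[i, lo + 1] <- A[i, lo + 1] + (1 - f)
    A[i, hi + 1] <- A[i, hi + 1] + f
  }
  A
}

nn_resize_apply <- function(x, Ah, Aw) {
  d <- dim(x)
  y1 <- Ah %*% matrix(x, d[1])                      # (Ho, W*C*N)
  ho <- nrow(Ah)
  y1 <- array(y1, c(ho, d[2], d[3], d[4]))
  y2 <- aperm(y1, c(2, 1, 3, 4))                    # (W, Ho, C, N)
  y3 <- Aw %*% matrix(y2, d[2])                     # (Wo, Ho*C*N)
  y3 <- array(y3, c(nrow(Aw), ho, d[3], d[4]))
  aperm(y3, c(2, 1, 3, 4))
}

nn_resize <- function(out_h, out_w) {
  l <- nn_layer("resize")
  l$out_h <- as.integer(out_h); l$out_w <- as.integer(out_w)
  l$fwd <- function(x, training = TRUE) {
    d <- dim(x)
    l$in_h <- d[1]; l$in_w <- d[2]
    if (d[1] == l$out_h && d[2] == l$out_w) { l$identity <- TRUE; return(x) }
    l$identity <- FALSE
    if (is.null(l$Ah) || nrow(l$Ah) != l$out_h || ncol(l$Ah) != d[1]) {
      l$Ah <- nn_interp_matrix(l$out_h, d[1])
      l$Aw <- nn_interp_matrix(l$out_w, d[2])
    }
    nn_resize_apply(x, l$Ah, l$Aw)
  }
  l$bwd <- function(gy) {
    if (isTRUE(l$identity)) return(gy)
    nn_resize_apply(gy, t(l$Ah), t(l$Aw))
  }
  l
}

## ---- dense / embedding ------------------------------------------------

# Dense layer on (D_in, N) matrices
nn_dense <- function(din, dout) {
  l <- nn_layer("dense")
  l$params <- list(w = nn_xavier(c(dout, din), din, dout), b = rep(0, dout))
  nn_zero_grads(l)
  l$fwd <- function(x, training = TRUE) {
    l$x <- x
    l$params$w %*% x + l$params$b
  }
  l$bwd <- function(gy) {
    l$grads$w <- l$grads$w + gy %*% t(l$x)
    l$grads$b <- l$grads$b + rowSums(gy)
    t(l$params$w) %*% gy
  }
  l
}

# Embedding table: fwd takes integer indices (1-based), returns (E, N)
nn_embedding <- function(n_codes, dim_emb) {
  l <- nn_layer("embedding")
  l$params <- list(w = array(stats::rnorm(dim_emb * n_codes, sd = 0.1),
                             dim = c(dim_emb, n_codes)))
  nn_zero_grads(l)
  l$fwd <- function(idx, training = TRUE) {
    l$idx <- as.integer(idx)
    l$params$w[, l$idx, drop = FALSE]
  }
  l$bwd <- function(gy) {
    agg <- rowsum(t(gy), l$idx)
    cols <- as.integer(rownames(agg))
    l$grads$w[, cols] <- l$grads$w[, cols] + t(agg)
    NULL
  }
  l
}

## ---- containers & optimizer -------------------------------------------

nn_sequential_fwd <- function(layers, x, training = TRUE) {
  for (l in layers) x <- l$fwd(x, training)
  x
}

nn_sequential_bwd <- function(layers, g) {
  for (l in rev(layers)) g <- l$bwd(g)
  g
}

nn_collect_layers <- function(x) {
  if (inherits(x, "nn_layer")) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, nn_collect_layers)))
  list()
}

nn_zero_all <- function(layers) {
  for (l in nn_collect_layers(layers)) nn_zero_grads(l)
  invisible(NULL)
}

# In-place Adam update over every parameter of every layer (C++ kernel;
# the moment buffers and parameters are updated without R-level copies)
nn_adam_step <- function(layers, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in nn_collect_layers(layers)) {
    if (!length(l$params)) next
    if (is.null(l$adam_m)) {
      l$adam_m <- lapply(l$params, function(p) p * 0)
      l$adam_v <- lapply(l$params, function(p) p * 0)
      l$adam_t <- 0L
    }
    l$adam_t <- l$adam_t + 1L
    lr_l <- lr * (l$lr_mult %||% 1)
    for (nm in names(l$params)) {
      cc_adam_update(l$params[[nm]], l$grads[[nm]], l$adam_m[[nm]],
                     l$adam_v[[nm]], lr_l, beta1, beta2, eps, l$adam_t)
    }
  }
  invisible(NULL)
}

# EMA update of a parameter snapshot toward the current weights (in place)
nn_ema_update <- function(layers, ema, decay) {
  ls <- nn_collect_layers(layers)
  for (i in seq_along(ls)) {
    p <- ls[[i]]$params
    for (nm in names(p)) cc_ema_update(ema[[i]][[nm]], p[[nm]], decay)
  }
  ema
}

# Deep-copied parameter snapshot / restore (parameters are updated in place,
# so snapshots must own their memory)
nn_get_state <- function(layers) {
  lapply(nn_collect_layers(layers), function(l) lapply(l$params, function(p) p + 0))
}

nn_set_state <- function(layers, state) {
  ls <- nn_collect_layers(layers)
  stopifnot(length(ls) == length(state))
  for (i in seq_along(ls)) ls[[i]]$params <- state[[i]]
  invisible(NULL)
}
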