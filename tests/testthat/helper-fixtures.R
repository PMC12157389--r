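# Shared fixtures: everything is generated in code at test time.

# tiny two-clutch cohort for fast unit tests (32 x 64 canvas, g = 8 latents)
tiny_design <- function(n_per_group = 6L, seed = 11L, ...) {
  cohort_design(
    genotypes = c("control", "mutA"),
    clutches = c("c1", "c2"),
    ages = "3dpf",
    assignment = list(c1 = c("control", "mutA"), c2 = c("control", "mutA")),
    n_per_group = n_per_group,
    image_shape = c(32L, 64L),
    seed = seed, ...)
}

tiny_vae_config <- function() {
  vae_config(c(32L, 64L), 8L, enc_channels = c(4L, 6L, 8L, 8L),
             dec_channels = c(8L, 8L, 8L, 4L, 4L), beta = 1e-4)
}

# central finite-difference gradient of scalar f at x
num_grad <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(max(abs(b)), 1e-8)
}

# all set partitions of 1..n (restricted-growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels, next_max) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible(NULL))
    }
    for (v in seq_len(next_max + 1)) {
      grow(c(labels, v), max(next_max, v))
    }
  }
  grow(integer(0), 0L)
  out
}

# brute-force pair-counting adjusted Rand index
ari_brute <- function(a, b) {
  n <- length(a)
  ss <- 0; sd_ <- 0; ds <- 0; dd <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) ss <- ss + 1
    else if (sa && !sb) sd_ <- sd_ + 1
    else if (!sa && sb) ds <- ds + 1
    else dd <- dd + 1
  }
  tot <- ss + sd_ + ds + dd
  e <- (ss + sd_) * (ss + ds) / tot
  m <- ((ss + sd_) + (ss + ds)) / 2
  if (m == e) return(0)
  (ss - e) / (m - e)
}
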