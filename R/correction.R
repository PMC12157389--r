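# Reference-clutch correction: encode -> forward-noise -> conditionally
# denoise with the clutch code swapped to the reference -> (optionally)
# decode. Genotype and age codes are never altered, so any post-correction
# grouping by genotype is unsupervised.

#' Select the reference clutch
#'
#' The clutch with the largest number of control samples; ties are broken
#' lexicographically by clutch label.
#'
#' @param coded_table label table with `clutch` and `control_flag` columns
#'   (e.g. the output of [build_condition_codes()]).
#' @return the reference clutch label.
#' @export
select_reference_clutch <- function(coded_table) {
  stopifnot(nrow(coded_table) > 0)
  ctrl <- coded_table[coded_table$control_flag, , drop = FALSE]
  if (nrow(ctrl) == 0) stop("no control samples in the table")
  counts <- table(ctrl$clutch)
  names(counts)[order(-as.vector(counts), names(counts))][1]
}

#' Correct samples into the style of a target clutch
#'
#' Every sample is encoded with the frozen VAE (posterior mean), pushed
#' through the forward diffusion process to `noise_steps`, then denoised by
#' the full reverse chain conditioned on (its own genotype code, the target
#' clutch, its own age code). Output is either the corrected latent
#' embedding or the decoded image.
#'
#' @param images list of H x W matrices or (H, W, N) array in `[-1, 1]`,
#'   aligned with the rows of `codes`.
#' @param codes coded table (rows aligned with `images`) carrying
#'   genotype_code / clutch_code / age_code.
#' @param target_clutch clutch code to restyle into, or `"AUTO"` to call
#'   [select_reference_clutch()].
#' @param vae trained `vae_model`.
#' @param denoiser trained `denoiser_model` (stores the condition levels and
#'   latent standardization from training).
#' @param schedule the [make_linear_schedule()] used in training.
#' @param seed integer seed for the noise injection, so corrected datasets
#'   are reproducible.
#' @param output_space `"embedding"` (D x N matrix of corrected latents) or
#'   `"image"` (list of H x W matrices in `[-1, 1]`).
#' @param noise_steps forward-noising depth (default: the full schedule T).
#' @param chunk samples per reverse-chain batch.
#' @return corrected embeddings (D x N matrix, columns named by sample_id)
#'   or a named list of corrected images; label metadata in `codes` is
#'   untouched.
#' @export
batch_correct <- function(images, codes, target_clutch = "AUTO", vae, denoiser,
                          schedule, seed = 1L,
                          output_space = c("embedding", "image"),
                          noise_steps = NULL, chunk = 128L) {
  output_space <- match.arg(output_space)
  lv <- denoiser$cond_levels
  if (is.null(lv)) stop("denoiser has no stored condition levels; train it with a condition_index")
  if (identical(target_clutch, "AUTO")) target_clutch <- select_reference_clutch(codes)
  if (!target_clutch %in% lv$clutch) {
    stop("unknown target clutch code '", target_clutch, "'")
  }
  if (vae$config$latent_grid != denoiser$config$latent_grid) {
    stop("config mismatch: VAE latent grid ", vae$config$latent_grid,
         " vs denoiser grid ", denoiser$config$latent_grid)
  }
  x <- images_to_array(images)
  n <- dim(x)[4]
  stopifnot(nrow(codes) == n)
  ci <- condition_index(codes, lv)
  ci$clutch <- rep(match(target_clutch, lv$clutch), n)
  tT <- if (is.null(noise_steps)) schedule$T else as.integer(noise_steps)
  stopifnot(tT >= 1, tT <= schedule$T)
  g <- denoiser$config$latent_grid; D <- g * g

  set.seed(seed)
  mu <- vae_encode(vae, x)$mu
  z0 <- (mu - denoiser$latent_shift) / denoiser$latent_scale
  out <- matrix(0, D, n)
  for (b0 in seq(1, n, by = chunk)) {
    ids <- b0:min(b0 + chunk - 1, n)
    sub <- list(genotype = ci$genotype[ids], clutch = ci$clutch[ids],
                age = ci$age[ids])
    zt <- forward_noise(z0[, ids, drop = FALSE], tT, NULL, schedule)
    attr(zt, "eps") <- NULL
    zarr <- array(zt, c(g, g, 1, length(ids)))
    zarr <- reverse_chain(zarr, tT, sub, denoiser, schedule)
    out[, ids] <- matrix(zarr, D)
  }
  out <- out * denoiser$latent_scale + denoiser$latent_shift
  colnames(out) <- codes$sample_id
  if (output_space == "embedding") return(out)
  dec <- vae_decode(vae, out)
  imgs <- lapply(seq_len(n), function(i) dec[, , 1, i])
  names(imgs) <- codes$sample_id
  imgs
}
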