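# High-level drivers reproducing the package's benchmark analyses on
# synthetic cohorts: the correction experiment (train VAE + conditional
# diffusion, correct to the reference clutch, score FID-cluster partitions
# against clutch and genotype ground truth) and the classifier experiment
# (pairwise genotype AUROC on corrected images).

#' Benchmark cohort design: four clutches, one unique mutant each, two ages
#'
#' The multi-clutch confounded design used by the package's end-to-end
#' validation: every clutch carries controls plus one clutch-exclusive
#' mutant genotype, profiled at two ages, with the default effect sizes
#' (strong clutch intensity style, strong genotype geometry, mild age
#' scale).
#'
#' @param n_per_group images per (genotype, clutch, age) cell.
#' @param seed cohort seed.
#' @return a [cohort_design()].
#' @export
benchmark_design <- function(n_per_group = 40L, seed = 1L) {
  cohort_design(
    genotypes = c("control", "mutA", "mutB", "mutC", "mutD"),
    clutches = c("c1", "c2", "c3", "c4"),
    ages = c("3dpf", "5dpf"),
    assignment = list(c1 = c("control", "mutA"), c2 = c("control", "mutB"),
                      c3 = c("control", "mutC"), c4 = c("control", "mutD")),
    n_per_group = n_per_group, image_shape = c(64L, 128L), seed = seed)
}

#' End-to-end reference-clutch correction experiment
#'
#' Generates (or takes) a labeled cohort, preprocesses it, builds the
#' condition codes, trains the VAE and the conditional latent diffusion
#' model, corrects every image into the reference clutch's style, and
#' scores the FID-cluster partitions of the held-out genotype groups
#' against the clutch and the genotype ground truth, before and after
#' correction. Lower clutch ARI after correction means better batch
#' removal; higher genotype ARI means held-out groups reunite by biology.
#'
#' @param design a [cohort_design()]; default [benchmark_design()] seeded
#'   with `seed`.
#' @param seed master seed for cohort, splits, weights and noise.
#' @param latent_grid VAE/diffusion latent grid side.
#' @param vae_epochs,ldm_epochs training epoch budgets.
#' @param vae_lr,ldm_lr learning rates.
#' @param T diffusion step count.
#' @param r_end terminal per-step noise variance of the linear schedule
#'   (the default leaves a terminal signal level comparable to the
#'   full-length schedule's).
#' @param base_channels U-Net base width.
#' @param keep_models return the trained models (large) as well.
#' @param verbose print stage progress.
#' @return list with `ari` (data.frame: partition x raw/corrected ARIs),
#'   `fid_raw`, `fid_corrected`, `reference_clutch`, `coded`, `timings`,
#'   and optionally `vae`, `denoiser`, plus the corrected embeddings.
#' @export
correction_experiment <- function(design = NULL, seed = 1L, latent_grid = 16L,
                                  vae_epochs = 6L, ldm_epochs = 120L,
                                  vae_lr = 2e-3, ldm_lr = 1.5e-3,
                                  T = 100L, r_end = 0.07,
                                  base_channels = 12L,
                                  keep_models = FALSE, verbose = FALSE) {
  tic <- function() proc.time()[[3]]
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- tic()
  if (is.null(design)) design <- benchmark_design(seed = seed)
  coh <- generate_cohort(design)
  pp <- preprocess_cohort(coh$images, labels = coh$labels,
                          target_shape = design$image_shape)
  imgs <- lapply(pp$images, to_model_range)
  coded <- build_condition_codes(pp$labels, seed = seed)
  sp <- split_train_val(coded, 0.8, seed = seed)
  val_ids <- match(sp$val, coded$sample_id)
  t_data <- tic() - t0

  vcfg <- vae_config(design$image_shape, latent_grid,
                     enc_channels = c(8L, 12L, 16L, 16L),
                     dec_channels = c(12L, 12L, 12L, 6L, 6L), beta = 1e-4)
  t0 <- tic()
  vfit <- fit_vae(imgs, vcfg, epochs = vae_epochs, lr = vae_lr,
                  batch_size = 32L, val_ids = val_ids, patience = vae_epochs,
                  seed = seed)
  t_vae <- tic() - t0
  say("VAE trained in %.0f s (val loss %.4f)", t_vae,
      utils::tail(vfit$report$val_loss, 1))

  t0 <- tic()
  mu <- vae_encode(vfit$model, imgs)$mu
  ci <- condition_index(coded)
  sched <- make_linear_schedule(T, r_end = r_end)
  dcfg <- denoiser_config(latent_grid = latent_grid,
                          base_channels = base_channels, emb_dim = 32L,
                          n_genotype = length(ci$levels$genotype),
                          n_clutch = length(ci$levels$clutch),
                          n_age = length(ci$levels$age))
  lfit <- fit_ldm(mu, ci, dcfg, sched, epochs = ldm_epochs, lr = ldm_lr,
                  batch_size = 80L, val_ids = val_ids, patience = ldm_epochs,
                  val_every = 10L, lr_schedule = "cosine", seed = seed)
  t_ldm <- tic() - t0
  say("diffusion model trained in %.0f s (val loss %.4f)", t_ldm,
      utils::tail(lfit$report$val_loss, 1))

  t0 <- tic()
  ref <- select_reference_clutch(coded)
  emb_cor <- batch_correct(imgs, coded, ref, vfit$model, lfit$model, sched,
                           seed = seed, output_space = "embedding",
                           chunk = 320L)
  t_cor <- tic() - t0
  say("corrected %d samples to clutch %s in %.0f s", ncol(emb_cor), ref, t_cor)

  # held-out genotype groups: mutants + held-out controls, per clutch & age
  ho <- coded$heldout_control | !coded$control_flag
  grp <- paste(coded$clutch, coded$genotype_code, sep = "::")[ho]
  geno_truth <- coded$genotype[ho]
  geno_truth[coded$heldout_control[ho]] <- "control"
  clutch_of_grp <- vapply(split(coded$clutch[ho], grp), `[`, "", 1)
  geno_of_grp <- vapply(split(geno_truth, grp), `[`, "", 1)
  score <- function(emb) {
    fid <- pairwise_fid(t(emb[, ho, drop = FALSE]), grp)
    kc <- length(unique(clutch_of_grp))
    kg <- length(unique(geno_of_grp))
    lc <- cluster_and_cut(fid, kc)$labels
    lg <- cluster_and_cut(fid, kg)$labels
    list(fid = fid,
         clutch = adjusted_rand_index(lc[names(clutch_of_grp)], clutch_of_grp),
         genotype = adjusted_rand_index(lg[names(geno_of_grp)], geno_of_grp))
  }
  raw <- score(mu)
  cor <- score(emb_cor)
  ari <- data.frame(partition = c("clutch", "genotype"),
                    raw = c(raw$clutch, raw$genotype),
                    corrected = c(cor$clutch, cor$genotype))
  out <- list(ari = ari, fid_raw = raw$fid, fid_corrected = cor$fid,
              reference_clutch = ref, coded = coded,
              embeddings_raw = mu, embeddings_corrected = emb_cor,
              timings = c(data = t_data, vae = t_vae, ldm = t_ldm,
                          correction = t_cor))
  if (keep_models) {
    out$vae <- vfit$model
    out$denoiser <- lfit$model
    out$schedule <- sched
    out$images <- imgs
  }
  out
}

#' Classifier discriminability experiment on a corrected cohort
#'
#' Builds a three-clutch cohort in which two mutant genotypes are generated
#' identically (in different clutches) and one is strongly geometry-
#' separated, corrects all images into the reference clutch's style, and
#' runs the all-pairs two-stage classifier AUROC over the mutants on the
#' corrected (decoded) images. Identically generated pairs should sit near
#' chance; geometry-separated pairs near 1.
#'
#' @param n_per_group images per (genotype, clutch, age) cell.
#' @param seed master seed.
#' @param ldm_epochs diffusion epoch budget; the default keeps the number
#'   of optimizer steps comparable to [correction_experiment()]'s on this
#'   smaller cohort.
#' @param ... forwarded to [correction_experiment()] (training budgets).
#' @return list with `auroc` (the AUROC matrix over mutant genotypes),
#'   `graph` (similarity graph at the 0.6 threshold), `twin_pair`,
#'   `separated_pairs`.
#' @export
classifier_experiment <- function(n_per_group = 60L, seed = 1L,
                                  ldm_epochs = 350L, vae_epochs = 10L, ...) {
  geo <- default_geometry()
  long <- utils::modifyList(geo, list(tail_len = geo$tail_len * 1.6,
                                      body_height = geo$body_height * 1.35))
  design <- cohort_design(
    genotypes = c("control", "twinA", "twinB", "longTail"),
    clutches = c("c1", "c2", "c3"), ages = "3dpf",
    assignment = list(c1 = c("control", "twinA"), c2 = c("control", "twinB"),
                      c3 = c("control", "longTail")),
    n_per_group = n_per_group, image_shape = c(64L, 128L),
    clutch_intensity_shift = 0.22,
    genotype_params = list(twinA = geo, twinB = geo, longTail = long),
    seed = seed)
  exp <- correction_experiment(design = design, seed = seed,
                               ldm_epochs = ldm_epochs, vae_epochs = vae_epochs,
                               keep_models = TRUE, ...)
  imgs_cor <- batch_correct(exp$images, exp$coded, exp$reference_clutch,
                            exp$vae, exp$denoiser, exp$schedule,
                            seed = seed + 1L, output_space = "image",
                            chunk = 320L)
  fam <- c(twinA = "famTwin", twinB = "famTwin", longTail = "famTail")
  au <- pairwise_genotype_auroc(imgs_cor, exp$coded$genotype, fam,
                                pairs = rbind(c("twinA", "twinB"),
                                              c("twinA", "longTail"),
                                              c("twinB", "longTail")),
                                seeds = seed + 0:2, stage1_epochs = 20L)
  muts <- c("twinA", "twinB", "longTail")
  graph <- build_similarity_graph(au[muts, muts], threshold = 0.6)
  list(auroc = au, graph = graph,
       twin_pair = c("twinA", "twinB"),
       separated_pairs = rbind(c("twinA", "longTail"), c("twinB", "longTail")),
       ari = exp$ari, correction = exp, images_corrected = imgs_cor)
}
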