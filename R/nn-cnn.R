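# Small train-from-scratch CNN classifier used by the pairwise genotype
# discriminability experiments: three strided convolutions with batch norm,
# global average pooling and a linear head. Stage-1 fine-tuning trains the
# whole network on a family dataset; stage-2 refits only the final
# classification layer (a logistic regression on the pooled trunk features)
# for one genotype pair.

nn_gap <- function() {
  l <- nn_layer("gap")
  l$fwd <- function(x, training = TRUE) {
    d <- dim(x)
    l$d <- d
    matrix(cc_block_sum2(x, d[1] * d[2])$sum, d[3], d[4]) / (d[1] * d[2])
  }
  l$bwd <- function(gy) {
    d <- l$d
    array(cc_block_expand(as.vector(gy) / (d[1] * d[2]), d[1] * d[2]), d)
  }
  l
}

# flatten (H, W, C, N) -> (H*W*C, N)
nn_flatten <- function() {
  l <- nn_layer("flatten")
  l$fwd <- function(x, training = TRUE) {
    l$d <- dim(x)
    matrix(x, prod(l$d[1:3]), l$d[4])
  }
  l$bwd <- function(gy) array(gy, l$d)
  l
}

cnn_init <- function(input_shape, channels = c(8L, 16L, 32L), n_classes = 2L,
                     pool_grid = c(2L, 4L), seed = 1L) {
  set.seed(seed)
  m <- new.env(parent = emptyenv())
  pool <- if (all(pool_grid == 1L)) list(nn_gap()) else
    list(nn_resize(pool_grid[1], pool_grid[2]), nn_flatten())
  m$trunk <- c(list(
    nn_conv(1, channels[1], stride = c(2L, 2L)), nn_batchnorm(channels[1]), nn_lrelu(),
    nn_conv(channels[1], channels[2], stride = c(2L, 2L)), nn_batchnorm(channels[2]), nn_lrelu(),
    nn_conv(channels[2], channels[3], stride = c(2L, 2L)), nn_batchnorm(channels[3]), nn_lrelu()),
    pool)
  m$trunk[[1]]$need_dx <- FALSE
  m$head <- nn_dense(channels[3] * prod(pool_grid), n_classes)
  m$input_shape <- input_shape
  class(m) <- "cnn_model"
  m
}

cnn_logits <- function(m, x, training = FALSE) {
  m$head$fwd(nn_sequential_fwd(m$trunk, x, training), training)
}

cnn_features <- function(m, x) {
  nn_sequential_fwd(m$trunk, x, training = FALSE)
}

# multiclass cross-entropy training with Adam
cnn_fit <- function(m, x, y, epochs = 10L, lr = 1e-3, batch_size = 32L,
                    seed = 1L) {
  set.seed(seed)
  n <- dim(x)[4]
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    for (b0 in seq(1, n, by = batch_size)) {
      ids <- ord[b0:min(b0 + batch_size - 1, n)]
      xb <- x[, , , ids, drop = FALSE]
      logits <- cnn_logits(m, xb, training = TRUE)
      p <- exp(sweep(logits, 2, apply(logits, 2, max)))
      p <- sweep(p, 2, colSums(p), "/")
      g <- p
      g[cbind(y[ids], seq_along(ids))] <- g[cbind(y[ids], seq_along(ids))] - 1
      g <- g / length(ids)
      nn_zero_all(list(m$trunk, m$head))
      nn_sequential_bwd(m$trunk, m$head$bwd(g))
      nn_adam_step(list(m$trunk, m$head), lr)
    }
  }
  invisible(m)
}

#' All-pairs genotype discriminability via two-stage fine-tuned classifiers
#'
#' For every unordered genotype pair: stage 1 trains a small convolutional
#' classifier on the union of the two genotypes' family datasets (every
#' genotype of both families plus all controls, multiclass); stage 2 refits
#' the final classification layer on the pair alone; AUROC is evaluated on
#' a held-out stratified split. The whole procedure is repeated for each
#' entry of `seeds` (fresh splits and initializations) and the AUROCs are
#' averaged; entries are then oriented to `max(a, 1 - a)` so they are
#' label-order invariant.
#'
#' @param images list of H x W matrices or (H, W, N) array.
#' @param genotypes length-N genotype label vector aligned with `images`.
#' @param family_map named character vector, mutant genotype -> family.
#'   Controls (the `control_label` genotype) belong to every family.
#' @param control_label the control genotype label.
#' @param pairs optional 2-column character matrix of genotype pairs to
#'   evaluate; default all unordered pairs of non-control genotypes plus
#'   each genotype vs control.
#' @param seeds integer vector of replicate seeds.
#' @param holdout_fraction held-out test fraction per genotype.
#' @param min_per_class genotypes with fewer samples are skipped (NaN entry,
#'   with a warning).
#' @param channels trunk widths of the classifier.
#' @param pool_grid spatial pooling grid before the classification head
#'   (`c(1, 1)` = global average pooling).
#' @param stage1_epochs,lr,batch_size stage-1 training hyperparameters.
#' @return square AUROC matrix over genotypes (class `auroc_matrix`,
#'   diagonal NA), with the family map attached as attribute `family_map`.
#' @export
pairwise_genotype_auroc <- function(images, genotypes, family_map,
                                    control_label = "control", pairs = NULL,
                                    seeds = c(1L, 2L, 3L),
                                    holdout_fraction = 0.4,
                                    min_per_class = 8L,
                                    channels = c(8L, 16L, 32L),
                                    pool_grid = c(2L, 4L),
                                    stage1_epochs = 10L, lr = 3e-3,
                                    batch_size = 32L) {
  x <- images_to_array(images)
  genotypes <- as.character(genotypes)
  stopifnot(dim(x)[4] == length(genotypes))
  gset <- sort(unique(genotypes))
  if (length(gset) < 2) stop("need at least 2 genotypes")
  muts <- setdiff(gset, control_label)
  if (!all(muts %in% names(family_map))) {
    stop("family_map must assign every mutant genotype to a family")
  }
  if (is.null(pairs)) {
    pairs <- t(utils::combn(muts, 2))
    if (control_label %in% gset) {
      pairs <- rbind(pairs, cbind(muts, control_label))
    }
  }
  fam_of <- function(g) if (g == control_label) character(0) else family_map[[g]]
  genos_of_families <- function(fams) {
    c(names(family_map)[family_map %in% fams], control_label)
  }
  auroc <- matrix(NA_real_, length(gset), length(gset),
                  dimnames = list(gset, gset))

  for (pi in seq_len(nrow(pairs))) {
    ga <- pairs[pi, 1]; gb <- pairs[pi, 2]
    na <- sum(genotypes == ga); nb <- sum(genotypes == gb)
    if (na < min_per_class || nb < min_per_class) {
      warning("pair ", ga, " vs ", gb, " skipped: fewer than ", min_per_class,
              " samples in a class")
      next
    }
    fams <- unique(c(fam_of(ga), fam_of(gb)))
    stage1_genos <- intersect(unique(c(genos_of_families(fams), ga, gb)), gset)
    vals <- numeric(0)
    for (sd_i in seeds) {
      set.seed(sd_i * 10007L + pi)
      # stratified holdout split over all stage-1 genotypes
      test_idx <- integer(0)
      for (g in stage1_genos) {
        idx <- which(genotypes == g)
        test_idx <- c(test_idx, sample(idx, max(1L, round(holdout_fraction * length(idx)))))
      }
      train_idx <- setdiff(which(genotypes %in% stage1_genos), test_idx)
      # stage 1: multiclass classifier over the family union
      cls <- match(genotypes, stage1_genos)
      mdl <- cnn_init(dim(x)[1:2], channels, length(stage1_genos),
                      pool_grid = pool_grid, seed = sd_i * 31L + 7L)
      cnn_fit(mdl, x[, , , train_idx, drop = FALSE], cls[train_idx],
              epochs = stage1_epochs, lr = lr, batch_size = batch_size,
              seed = sd_i * 131L + pi)
      # stage 2: logistic head on trunk features for the pair only
      tr_pair <- train_idx[genotypes[train_idx] %in% c(ga, gb)]
      te_pair <- test_idx[genotypes[test_idx] %in% c(ga, gb)]
      ftr <- t(cnn_features(mdl, x[, , , tr_pair, drop = FALSE]))
      fte <- t(cnn_features(mdl, x[, , , te_pair, drop = FALSE]))
      ytr <- as.integer(genotypes[tr_pair] == ga)
      yte <- as.integer(genotypes[te_pair] == ga)
      # ridge-regularized logistic head: the pair training set is small
      # relative to the trunk feature dimension
      fit <- glmnet::glmnet(ftr, ytr, family = "binomial", alpha = 0,
                            lambda = 0.05)
      sc <- as.vector(stats::predict(fit, fte))
      vals <- c(vals, as.numeric(suppressMessages(
        pROC::auc(pROC::roc(yte, sc, quiet = TRUE, direction = "<")))))
    }
    a <- mean(vals)
    a <- max(a, 1 - a)
    auroc[ga, gb] <- a; auroc[gb, ga] <- a
  }
  attr(auroc, "family_map") <- family_map
  class(auroc) <- c("auroc_matrix", class(auroc))
  auroc
}
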