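# Evaluation stack: group Frechet distances in a feature space, FID-matrix
# hierarchical clustering scored by the adjusted Rand index, and all-pairs
# binary-classifier AUROC with the similarity graph.

#' Per-group feature statistics
#'
#' Mean vector and covariance matrix per group, with an analytic
#' Schafer-Strimmer-style shrinkage of the off-diagonal correlations toward
#' zero (i.e. a convex blend of the covariance toward its diagonal), applied
#' whenever the group is smaller than the feature dimension.
#'
#' @param features N x D matrix (rows = samples).
#' @param groups length-N grouping vector.
#' @param shrink `"auto"` (shrink when n < D), `"always"` or `"never"`.
#' @return named list of `group_stats` objects (fields mu, sigma, n).
#' @export
group_stats <- function(features, groups, shrink = c("auto", "always", "never")) {
  shrink <- match.arg(shrink)
  stopifnot(is.matrix(features), nrow(features) == length(groups))
  out <- list()
  for (gname in sort(unique(as.character(groups)))) {
    xg <- features[as.character(groups) == gname, , drop = FALSE]
    n <- nrow(xg)
    if (n < 2) stop("singleton group '", gname, "': need n >= 2 for covariance")
    mu <- colMeans(xg)
    do_shrink <- shrink == "always" || (shrink == "auto" && n < ncol(xg))
    sigma <- if (do_shrink) shrunk_cov(xg) else stats::cov(xg)
    out[[gname]] <- structure(list(mu = mu, sigma = sigma, n = n),
                              class = "group_stats")
  }
  out
}

# Schafer-Strimmer shrinkage of off-diagonal correlations toward zero;
# lambda is the analytic optimum sum(var_hat(r_ij)) / sum(r_ij^2), i != j.
shrunk_cov <- function(x) {
  n <- nrow(x); p <- ncol(x)
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1
  xs <- scale(x, center = TRUE, scale = sds)
  r <- crossprod(xs) / (n - 1)
  w2 <- crossprod(xs^2) # sum_k w_kij^2 with w_kij = xs_ki * xs_kj
  wbar <- r * (n - 1) / n
  var_r <- n / (n - 1)^3 * (w2 - n * wbar^2)
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  lambda <- if (denom <= 0) 1 else min(1, max(0, sum(var_r[off]) / denom))
  r_star <- r * (1 - lambda)
  diag(r_star) <- 1
  sweep(sweep(r_star, 1, sds, "*"), 2, sds, "*")
}

#' Frechet distance between two Gaussian group summaries
#'
#' `||mu_X - mu_Y||^2 + Tr(S_X + S_Y - 2 (S_X S_Y)^{1/2})`, the distance
#' under which two sample groups are compared as Gaussians in feature
#' space. The matrix square root is computed via the symmetric eigenform
#' `(S_X^{1/2} S_Y S_X^{1/2})^{1/2}` with negative eigenvalues clipped at
#' a -1e-8 tolerance.
#'
#' @param stats_x,stats_y `group_stats` objects of equal feature dimension.
#' @return nonnegative scalar.
#' @export
frechet_distance <- function(stats_x, stats_y) {
  if (length(stats_x$mu) != length(stats_y$mu)) stop("feature dimension mismatch")
  sx <- as.matrix(stats_x$sigma); sy <- as.matrix(stats_y$sigma)
  tol <- 1e-8
  ex <- eigen((sx + t(sx)) / 2, symmetric = TRUE)
  scale_x <- max(abs(ex$values), 1)
  if (min(ex$values) < -tol * scale_x) stop("covariance of X is not PSD")
  sqx <- ex$vectors %*% (sqrt(pmax(ex$values, 0)) * t(ex$vectors))
  m <- sqx %*% sy %*% sqx
  em <- eigen((m + t(m)) / 2, symmetric = TRUE)
  scale_m <- max(abs(em$values), 1)
  if (min(em$values) < -tol * scale_m) stop("covariance product is not PSD")
  tr_sqrt <- sum(sqrt(pmax(em$values, 0)))
  d <- sum((stats_x$mu - stats_y$mu)^2) +
    sum(diag(sx)) + sum(diag(sy)) - 2 * tr_sqrt
  max(d, 0)
}

# flatten images / arrays / matrices into an N x D feature matrix
as_feature_matrix <- function(x) {
  if (is.list(x)) {
    t(vapply(x, as.vector, numeric(length(x[[1]]))))
  } else if (!is.null(dim(x)) && length(dim(x)) >= 3) {
    d <- dim(x)
    n <- d[length(d)]
    t(matrix(x, prod(d[-length(d)]), n))
  } else if (is.matrix(x)) {
    x
  } else {
    stop("cannot interpret features")
  }
}

#' Pairwise Frechet distance matrix over sample groups
#'
#' Features are flattened embeddings (`feature_space = "latent"`; a D x N
#' embedding matrix should be passed transposed, samples in rows) or
#' flattened images (`"pixel"`), the latter optionally reduced by a shared
#' linear projection (PCA fitted on all samples) to at most `project_dim`
#' dimensions before covariance estimation.
#'
#' @param features N x D matrix, list of images, or (H, W, N) array.
#' @param groups length-N grouping vector (e.g. clutch x genotype-label).
#' @param feature_space `"latent"` or `"pixel"`.
#' @param project_dim cap on the pixel-space projection dimension.
#' @param shrink covariance shrinkage mode, see [group_stats()].
#' @return symmetric matrix of class `fid_matrix` with zero diagonal.
#' @export
pairwise_fid <- function(features, groups, feature_space = c("latent", "pixel"),
                         project_dim = 256L, shrink = "auto") {
  feature_space <- match.arg(feature_space)
  fm <- as_feature_matrix(features)
  groups <- as.character(groups)
  stopifnot(nrow(fm) == length(groups))
  if (feature_space == "pixel" && ncol(fm) > project_dim) {
    k <- min(project_dim, nrow(fm) - 1L)
    pc <- stats::prcomp(fm, center = TRUE, rank. = k)
    fm <- pc$x
  }
  st <- group_stats(fm, groups, shrink = shrink)
  gn <- names(st)
  k <- length(gn)
  # per-group covariance square roots are reused across all pairs
  tol <- 1e-8
  sq <- lapply(st, function(g) {
    sg <- (g$sigma + t(g$sigma)) / 2
    ev <- eigen(sg, symmetric = TRUE)
    if (min(ev$values) < -tol * max(abs(ev$values), 1))
      stop("covariance of a group is not PSD")
    ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  })
  trs <- vapply(st, function(g) sum(diag(g$sigma)), 0)
  fid <- matrix(0, k, k, dimnames = list(gn, gn))
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      m <- sq[[i]] %*% st[[j]]$sigma %*% sq[[i]]
      em <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)
      if (min(em$values) < -tol * max(abs(em$values), 1))
        stop("covariance product is not PSD")
      d <- sum((st[[i]]$mu - st[[j]]$mu)^2) + trs[i] + trs[j] -
        2 * sum(sqrt(pmax(em$values, 0)))
      d <- max(d, 0)
      fid[i, j] <- d; fid[j, i] <- d
    }
  }
  class(fid) <- c("fid_matrix", class(fid))
  fid
}

#' Hierarchically cluster a distance matrix and cut into k groups
#'
#' Agglomerative clustering on the precomputed Frechet distance matrix,
#' flat labels from cutting the tree, and the dendrogram serialized as a
#' Newick string.
#'
#' @param fid symmetric distance matrix (e.g. from [pairwise_fid()]).
#' @param k flat cluster count, between 2 and the number of groups.
#' @param linkage `"average"` (default), `"complete"` or `"ward"`.
#' @return list with `labels` (named integer vector), `hclust`, `newick`.
#' @export
cluster_and_cut <- function(fid, k, linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  ng <- nrow(fid)
  if (k < 2 || k > ng) stop("k out of range 2..", ng)
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(stats::as.dist(fid), method = method)
  labels <- stats::cutree(hc, k = k)
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(labels = labels, hclust = hc, newick = newick)
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting ARI with the permutation-model expected index, via the
#' contingency-table closed form.
#'
#' @param labels_a,labels_b equal-length label vectors (length >= 2).
#' @return scalar in `[-1, 1]`; 1 for identical partitions, ~0 at chance.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("length mismatch")
  n <- length(labels_a)
  stopifnot(n >= 2)
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(0)
  (sum_ij - expected) / (maxi - expected)
}

#' Morphological-similarity graph from an AUROC matrix
#'
#' Nodes are genotypes; an undirected edge joins two genotypes whose
#' pairwise classifier AUROC falls strictly below `threshold` (high
#' misclassification = similar morphology). NA entries give no edge.
#'
#' @param auroc square symmetric AUROC matrix with genotype dimnames.
#' @param threshold strict upper AUROC bound for an edge (default 0.6).
#' @return list with `graph` (igraph object) and `edges` (data.frame
#'   from, to, auroc).
#' @export
build_similarity_graph <- function(auroc, threshold = 0.6) {
  gn <- rownames(auroc)
  edges <- data.frame(from = character(0), to = character(0), auroc = numeric(0))
  k <- nrow(auroc)
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      v <- auroc[i, j]
      if (!is.na(v) && v < threshold) {
        edges <- rbind(edges, data.frame(from = gn[i], to = gn[j], auroc = v))
      }
    }
  }
  graph <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = data.frame(name = gn))
  list(graph = graph, edges = edges)
}
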