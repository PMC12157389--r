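# Evaluation stack: Frechet distance closed forms, FID matrices,
# hierarchical clustering, the adjusted Rand index, and the similarity graph.

gs <- function(mu, sigma) {
  structure(list(mu = mu, sigma = as.matrix(sigma), n = 10L),
            class = "group_stats")
}

test_that("frechet_distance matches the 1-D closed forms exactly", {
  expect_lt(abs(frechet_distance(gs(0, 1), gs(0, 1))), 1e-10)
  # means 0 vs 2, unit variances: 4 + (1 + 1 - 2) = 4
  expect_lt(abs(frechet_distance(gs(0, 1), gs(2, 1)) - 4), 1e-10)
  # means equal, variances 1 vs 4: 1 + 4 - 2*2 = 1
  expect_lt(abs(frechet_distance(gs(0, 1), gs(0, 4)) - 1), 1e-10)
  expect_error(frechet_distance(gs(c(0, 0), diag(2)), gs(0, 1)), "dimension")
  expect_error(frechet_distance(gs(c(0, 0), matrix(c(1, 2, 2, 1), 2)),
                                gs(c(0, 0), diag(2))), "not PSD")
})

test_that("frechet_distance agrees with the diagonal-covariance closed form", {
  set.seed(14)
  for (d in c(2, 4, 7)) {
    mu1 <- rnorm(d); mu2 <- rnorm(d)
    v1 <- runif(d, 0.2, 3); v2 <- runif(d, 0.2, 3)
    closed <- sum((mu1 - mu2)^2) + sum(v1 + v2 - 2 * sqrt(v1 * v2))
    expect_lt(abs(frechet_distance(gs(mu1, diag(v1, d)), gs(mu2, diag(v2, d))) -
                    closed), 1e-8)
  }
})

test_that("group statistics shrink small-n covariances to valid PSD matrices", {
  set.seed(15)
  st <- group_stats(matrix(rnorm(240), 8, 30), rep("g1", 8)) # n = 8 < D = 30
  sg <- st$g1$sigma
  expect_true(isSymmetric(sg, tol = 1e-12))
  expect_gte(min(eigen(sg, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_error(group_stats(matrix(rnorm(10), 1), "solo"), "singleton group 'solo'")
})

test_that("pairwise_fid is symmetric, zero for duplicated groups, and names singletons", {
  set.seed(16)
  block <- matrix(rnorm(20 * 6), 20, 6)
  feats <- rbind(block, block, matrix(rnorm(20 * 6, mean = 5), 20, 6))
  grp <- rep(c("dupA", "dupB", "far"), each = 20)
  fid <- pairwise_fid(feats, grp)
  expect_lt(fid["dupA", "dupB"], 1e-8)
  expect_gt(fid["dupA", "far"], 1)
  expect_true(all(abs(fid - t(fid)) < 1e-8))
  expect_true(all(diag(fid) == 0))
  expect_error(pairwise_fid(feats[c(1:20, 21), ], c(rep("a", 20), "lonely")),
               "lonely")
})

test_that("pixel-space features are reduced by a shared projection before covariance", {
  set.seed(17)
  imgs <- replicate(30, matrix(rnorm(32 * 32), 32, 32), simplify = FALSE)
  fid <- pairwise_fid(imgs, rep(c("a", "b"), 15), feature_space = "pixel",
                      project_dim = 10L)
  expect_identical(dim(fid), c(2L, 2L))
  expect_true(all(is.finite(fid)))
})

test_that("hierarchical clustering recovers separable structure and serializes a tree", {
  d <- matrix(10, 9, 9) + matrix(runif(81), 9, 9)
  d <- (d + t(d)) / 2
  for (b in 0:2) d[b * 3 + 1:3, b * 3 + 1:3] <- 0.1
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("g", 1:9)
  res <- cluster_and_cut(d, k = 3)
  expect_identical(adjusted_rand_index(res$labels, rep(1:3, each = 3)), 1)
  expect_match(res$newick, "^\\(")
  res9 <- cluster_and_cut(d, k = 9)
  expect_length(unique(res9$labels), 9)
  expect_error(cluster_and_cut(d, k = 1), "out of range")
})

test_that("average-linkage merge heights match a brute-force agglomeration oracle", {
  # 4-group toy distances with a known merge order
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 1
  d["a", "c"] <- d["c", "a"] <- 6
  d["b", "c"] <- d["c", "b"] <- 8
  d["a", "d"] <- d["d", "a"] <- 11
  d["b", "d"] <- d["d", "b"] <- 12
  d["c", "d"] <- d["d", "c"] <- 4
  hc <- cluster_and_cut(d, k = 2)$hclust
  # oracle: merge (a,b) at 1; (c,d) at 4; then average linkage
  # d({a,b},{c,d}) = (6 + 8 + 11 + 12) / 4 = 9.25
  expect_equal(hc$height, c(1, 4, 9.25))
  labs <- cluster_and_cut(d, k = 2)$labels
  expect_identical(labs[["a"]], labs[["b"]])
  expect_identical(labs[["c"]], labs[["d"]])
  expect_false(labs[["a"]] == labs[["c"]])
})

test_that("adjusted_rand_index reproduces its closed-form examples", {
  expect_identical(adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)
  expect_identical(adjusted_rand_index(rep(1, 6), c(1, 2, 3, 1, 2, 3)), 0)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2, 2), c(1, 1, 2, 2, 1)), 1 / 6)
  expect_error(adjusted_rand_index(1:3, 1:4), "length mismatch")
})

test_that("adjusted_rand_index matches brute-force pair counting on random partitions", {
  set.seed(18)
  for (i in 1:25) {
    n <- sample(4:9, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), ari_brute(a, b))
  }
  # and the independent mclust implementation agrees
  skip_if_not_installed("mclust")
  for (i in 1:10) {
    a <- sample(1:4, 12, replace = TRUE)
    b <- sample(1:4, 12, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
})

test_that("the similarity graph connects exactly the low-AUROC pairs", {
  au <- matrix(0.95, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(au) <- NA
  g0 <- build_similarity_graph(au)
  expect_identical(nrow(g0$edges), 0L)
  expect_equal(igraph::vcount(g0$graph), 4)
  au["a", "b"] <- au["b", "a"] <- 0.55
  au["c", "d"] <- au["d", "c"] <- 0.60 # boundary: strict inequality, no edge
  au["a", "c"] <- au["c", "a"] <- NA  # skipped pair, no edge
  g1 <- build_similarity_graph(au, threshold = 0.6)
  expect_identical(nrow(g1$edges), 1L)
  expect_setequal(c(g1$edges$from, g1$edges$to), c("a", "b"))
  expect_equal(igraph::ecount(g1$graph), 1)
})
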