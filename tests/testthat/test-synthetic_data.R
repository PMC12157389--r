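# Synthetic cohort generator: rendering determinism, style injection,
# factorization of genotype/clutch/age effects.

test_that("rendering is deterministic given the RNG state and scales monotonically", {
  geo <- default_geometry()
  set.seed(5); a <- render_individual(geo, 1.0, c(64L, 128L))
  set.seed(5); b <- render_individual(geo, 1.0, c(64L, 128L))
  expect_identical(a, b)
  set.seed(5); big <- render_individual(geo, 1.3, c(64L, 128L))
  expect_gt(sum(big > 0), sum(a > 0))
  expect_true(all(is.finite(a)) && min(a) >= 0 && max(a) <= 1)
  # single connected-ish silhouette: every foreground column interval is contiguous
  fg_cols <- which(colSums(a > 0) > 0)
  expect_identical(fg_cols, seq(min(fg_cols), max(fg_cols)))
})

test_that("geometry that cannot fit the canvas is rejected", {
  geo <- default_geometry()
  geo$tail_len <- 2
  set.seed(1)
  expect_error(render_individual(geo, 1, c(64L, 128L)), "silhouette overflow")
})

test_that("a tail-length difference only changes pixels in the tail region", {
  geo1 <- default_geometry(); geo1$jitter <- 0
  geo2 <- geo1; geo2$tail_len <- geo1$tail_len * 1.5
  set.seed(3); a <- render_individual(geo1, 1, c(64L, 128L))
  set.seed(3); b <- render_individual(geo2, 1, c(64L, 128L))
  diff <- which(a != b, arr.ind = TRUE)
  expect_gt(nrow(diff), 0)
  # tail pixels live right of the body centre and inside the tail band,
  # which is narrower than the body and in the right part of the canvas
  expect_true(all(diff[, "col"] > 128 * 0.24))
  body_rows <- range(which(rowSums(a > 0) > 0))
  expect_true(all(diff[, "row"] >= body_rows[1] & diff[, "row"] <= body_rows[2]))
  expect_lt(diff(range(diff[, "row"])), diff(body_rows))
})

test_that("clutch style injection is an affine map with additive noise on the foreground", {
  px <- matrix(0, 10, 10); px[3:6, 3:6] <- 0.5
  expect_identical(inject_clutch_style(px, 0, 0), px)
  styled <- inject_clutch_style(px, 0.2, 0)
  expect_equal(styled[3:6, 3:6], matrix(0.7, 4, 4))
  expect_true(all(styled[px == 0] == 0))
  gained <- inject_clutch_style(px, 0.1, 0, clutch_contrast_gain = 1.2)
  expect_equal(gained[4, 4], 1.2 * 0.5 + 0.1)
  expect_error(inject_clutch_style(px, 2, 0), "degenerate style")
})

test_that("noise injection matches the Monte-Carlo folded-normal oracle", {
  px <- matrix(0, 20, 40); px[5:15, 5:35] <- 0.5
  sigma <- 0.05
  set.seed(42)
  changes <- replicate(200, {
    styled <- inject_clutch_style(px, 0, sigma)
    mean(abs(styled[px > 0] - px[px > 0]))
  })
  # E|N(0, sigma)| = sigma * sqrt(2/pi); clipping is negligible at 0.5 +- 3 sd
  oracle <- sigma * sqrt(2 / pi)
  se <- sd(changes) / sqrt(length(changes))
  expect_lt(abs(mean(changes) - oracle), 4 * se + 1e-4)
})

test_that("generate_cohort enumerates the design and is bit-reproducible", {
  des <- cohort_design(
    genotypes = c("control", "m1", "m2", "m3"),
    clutches = c("A", "B", "C"),
    ages = c("3dpf", "5dpf"),
    assignment = list(A = c("control", "m1"), B = c("control", "m2"),
                      C = c("control", "m3")),
    n_per_group = 5L, image_shape = c(32L, 64L), seed = 7L)
  coh <- generate_cohort(des)
  expect_length(coh$images, 3 * 2 * 2 * 5)
  expect_identical(nrow(coh$labels), 60L)
  expect_false(any(duplicated(coh$labels$sample_id)))
  expect_identical(as.vector(table(coh$labels$clutch)), rep(20L, 3))
  coh2 <- generate_cohort(des)
  expect_identical(coh$images, coh2$images)
  expect_identical(coh$labels, coh2$labels)
})

test_that("designs violating the control-in-every-clutch invariant are rejected", {
  expect_error(
    cohort_design(genotypes = c("control", "m1"), clutches = c("A", "B"),
                  assignment = list(A = c("control", "m1"), B = "m1")),
    "control genotype")
  expect_error(
    cohort_design(genotypes = "control", clutches = "A",
                  assignment = stats::setNames(list(character(0)), "A")),
    "empty assignment|control genotype")
})

test_that("with clutch effects disabled, same-genotype groups match across clutches", {
  des <- tiny_design(n_per_group = 20L, seed = 2L,
                     clutch_intensity_shift = 0, clutch_noise_sigma = 0)
  coh <- generate_cohort(des)
  ctrl <- coh$labels$genotype == "control"
  m1 <- sapply(coh$images[coh$labels$sample_id[ctrl & coh$labels$clutch == "c1"]], mean)
  m2 <- sapply(coh$images[coh$labels$sample_id[ctrl & coh$labels$clutch == "c2"]], mean)
  # group means equal within sampling noise of the geometry jitter
  expect_lt(abs(mean(m1) - mean(m2)),
            3 * sqrt(var(m1) / length(m1) + var(m2) / length(m2)) + 1e-4)
  # and the cross-clutch Frechet distance is comparable to a within-clutch split
  feats <- t(sapply(coh$images[ctrl], as.vector))
  cl <- coh$labels$clutch[ctrl]
  half <- rep(c("h1", "h2"), length.out = sum(cl == "c1"))
  fid_between <- pairwise_fid(feats, cl, feature_space = "pixel", project_dim = 20L)
  fid_within <- pairwise_fid(feats[cl == "c1", ], half, feature_space = "pixel",
                             project_dim = 20L)
  expect_lt(fid_between["c1", "c2"], 4 * fid_within["h1", "h2"] + 1)
})

test_that("with genotype effects disabled, FID clustering recovers the clutch partition", {
  des <- cohort_design(
    genotypes = "control", clutches = c("A", "B", "C"), ages = "3dpf",
    n_per_group = 24L, image_shape = c(32L, 64L), seed = 9L)
  coh <- generate_cohort(des)
  # two pseudo-replicate groups per clutch
  grp <- paste(coh$labels$clutch, rep(c("r1", "r2"), length.out = nrow(coh$labels)))
  feats <- t(sapply(coh$images, as.vector))
  fid <- pairwise_fid(feats, grp, feature_space = "pixel", project_dim = 30L)
  labs <- cluster_and_cut(fid, k = 3)$labels
  truth <- substr(names(labs), 1, 1)
  expect_gte(adjusted_rand_index(labs, truth), 0.9)
})

test_that("genotype_params overrides make genotypes identically generated", {
  geo <- default_geometry()
  des <- cohort_design(
    genotypes = c("control", "twinA", "twinB"), clutches = "A", ages = "3dpf",
    n_per_group = 4L, image_shape = c(32L, 64L),
    genotype_params = list(twinA = geo, twinB = geo), seed = 3L)
  coh <- generate_cohort(des)
  pa <- coh$images[coh$labels$sample_id[coh$labels$genotype == "twinA"]]
  pb <- coh$images[coh$labels$sample_id[coh$labels$genotype == "twinB"]]
  expect_equal(mean(sapply(pa, function(m) sum(m > 0))),
               mean(sapply(pb, function(m) sum(m > 0))),
               tolerance = 0.15)
})
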