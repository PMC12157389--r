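# Preprocessing: masking, edge-truncation QC, spatial normalization,
# intensity inversion and pipeline properties.

test_that("apply_mask zeroes the background and rejects degenerate input", {
  img <- matrix(0.8, 10, 12)
  ones <- matrix(1L, 10, 12)
  expect_equal(unclass(apply_mask(img, ones)), img, ignore_attr = TRUE)
  expect_error(apply_mask(img, matrix(0L, 10, 12)), "empty mask")
  expect_error(apply_mask(img, matrix(1L, 5, 12)), "shape mismatch")
  half <- ones; half[, 7:12] <- 0L
  out <- apply_mask(img, half)
  expect_true(all(out[, 1:6] == 0.8) && all(out[, 7:12] == 0))
})

test_that("edge truncation drops only masks touching the lateral bands", {
  W <- 794L
  m <- matrix(0L, 20, W)
  m[10, 4] <- 1L # 0-based column 3, inside [0, 5)
  expect_identical(edge_truncation_filter(m, 5L), "drop")
  m2 <- matrix(0L, 20, W); m2[5:15, 11:701] <- 1L
  expect_identical(edge_truncation_filter(m2, 5L), "keep")
  m3 <- matrix(0L, 20, W); m3[1, 300:400] <- 1L # touches top row only
  expect_identical(edge_truncation_filter(m3, 5L), "keep")
  m4 <- matrix(0L, 20, W); m4[10, W - 2] <- 1L # right band
  expect_identical(edge_truncation_filter(m4, 5L), "drop")
  expect_identical(edge_truncation_filter(m, 0L), "keep")
})

test_that("spatial_normalize emits exactly the target shape, centered", {
  img <- matrix(0, 50, 120)
  img[20:30, 40:80] <- 0.6
  out <- spatial_normalize(img, c(200L, 794L))
  expect_identical(dim(out), c(200L, 794L))
  expect_identical(sum(out > 0), sum(img > 0))
  # fixed point: already cropped-and-centered input is unchanged
  out2 <- spatial_normalize(out, c(200L, 794L))
  expect_equal(unclass(out2), unclass(out), ignore_attr = TRUE)
  expect_error(spatial_normalize(matrix(0, 5, 5), c(4L, 4L)), "empty foreground")
  big <- matrix(1, 10, 10)
  expect_error(spatial_normalize(big, c(8L, 20L)), "oversize foreground")
})

test_that("a single foreground pixel lands on the center cell (ties to top-left)", {
  # brute-force oracle over small canvases: after cropping to the 1x1 box,
  # the pad split is floor((T-1)/2) on top/left, so the pixel lands at
  # floor((T-1)/2) + 1 regardless of where it started
  for (th in 4:6) for (tw in 5:7) {
    expected <- c((th - 1L) %/% 2L + 1L, (tw - 1L) %/% 2L + 1L)
    for (r in c(1L, 3L)) for (cc in c(2L, 8L)) {
      img <- matrix(0, 9, 9); img[r, cc] <- 1
      out <- spatial_normalize(img, c(th, tw))
      expect_identical(unname(which(out > 0, arr.ind = TRUE)[1, ]), expected)
    }
  }
})

test_that("invert_intensity is an involution acting only on the foreground", {
  img <- matrix(0, 8, 8)
  img[3:5, 3:5] <- c(0.2, 0.5, 1, 0.7, 0.1, 0.9, 0.4, 0.3, 0.6)
  mask <- (img > 0) * 1L
  inv <- invert_intensity(img, max_range = 1, mask = mask)
  expect_equal(inv[3, 3], 0.8)
  expect_true(all(inv[mask == 0] == 0))
  back <- invert_intensity(inv, max_range = 1, mask = mask)
  expect_equal(unclass(back), unclass(img), ignore_attr = TRUE)
  # 8-bit: per-pixel 255 - v on the foreground, max maps to range minimum
  img8 <- matrix(0, 4, 4); img8[2, 2] <- 255; img8[2, 3] <- 100
  m8 <- (img8 > 0) * 1L
  inv8 <- invert_intensity(img8, max_range = 255, mask = m8)
  expect_identical(inv8[2, 2], 0)
  expect_identical(inv8[2, 3], 155)
  expect_identical(inv8[1, 1], 0)
})

test_that("the geometric pipeline stages are idempotent and conserve foreground", {
  set.seed(21)
  img <- render_individual(default_geometry(), 1, c(64L, 128L))
  mask <- synthetic_mask(img)
  r1 <- preprocess_image(img, mask, target_shape = c(64L, 128L), invert = FALSE)
  expect_true(r1$keep)
  m1 <- (attr(r1$image, "foreground")) * 1L
  r2 <- preprocess_image(r1$image, m1, target_shape = c(64L, 128L), invert = FALSE)
  expect_equal(unclass(r2$image), unclass(r1$image), ignore_attr = TRUE)
  expect_identical(sum(r1$image > 0), sum(img > 0))
  # with inversion, a second inversion restores the geometric output
  inv <- invert_intensity(r1$image)
  expect_identical(sum(attr(inv, "foreground")), sum(mask == 1))
  expect_equal(unclass(invert_intensity(inv)), unclass(r1$image), ignore_attr = TRUE)
})

test_that("preprocess_cohort reports QC decisions and filters labels", {
  des <- tiny_design(n_per_group = 3L, seed = 4L)
  coh <- generate_cohort(des)
  # corrupt one mask so it touches the left band
  bad_id <- coh$labels$sample_id[1]
  coh$images[[bad_id]][5, 1:3] <- 0.5
  pp <- preprocess_cohort(coh$images, labels = coh$labels,
                          target_shape = c(32L, 64L))
  expect_identical(nrow(pp$qc), nrow(coh$labels))
  expect_false(pp$qc$kept[pp$qc$sample_id == bad_id])
  expect_identical(pp$qc$reason[pp$qc$sample_id == bad_id], "edge")
  expect_false(bad_id %in% pp$labels$sample_id)
  expect_identical(length(pp$images), sum(pp$qc$kept))
})

test_that("model-range mapping is invertible", {
  img <- matrix(runif(20), 4, 5)
  expect_equal(from_model_range(to_model_range(img)), img)
  expect_equal(range(to_model_range(matrix(c(0, 1), 1, 2))), c(-1, 1))
})
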