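# Standardization of raw masked images: background removal, edge-truncation
# QC, centering/cropping/padding to a fixed shape and intensity inversion.
# Coordinate convention: row-major, 0-based columns in the edge rule,
# half-open ranges.

#' Zero out everything outside a segmentation mask
#'
#' Pixels where the mask is 0 are set to the range minimum ("black");
#' foreground pixels are unchanged.
#'
#' @param image H x W intensity matrix.
#' @param mask binary H x W mask (1 = organism foreground).
#' @return masked image with a logical `foreground` attribute.
#' @export
apply_mask <- function(image, mask) {
  if (!all(dim(image) == dim(mask))) stop("shape mismatch between image and mask")
  if (!any(mask > 0)) stop("empty mask")
  image[mask == 0] <- 0
  attr(image, "foreground") <- mask > 0
  image
}

#' Keep/drop decision for masks touching the lateral image edges
#'
#' A sample is dropped iff any foreground pixel falls in the left or right
#' `boundary_px`-wide column band (columns `[0, boundary_px)` or
#' `[W - boundary_px, W)`, 0-based). The top and bottom edges never trigger
#' a drop: the organism is only ever truncated along the long axis.
#'
#' @param mask binary H x W mask.
#' @param boundary_px band width in pixels (default 5).
#' @return `"keep"` or `"drop"`.
#' @export
edge_truncation_filter <- function(mask, boundary_px = 5L) {
  W <- ncol(mask)
  stopifnot(boundary_px >= 0, boundary_px < W / 2)
  if (boundary_px == 0) return("keep")
  cols <- c(seq_len(boundary_px), seq.int(W - boundary_px + 1L, W))
  if (any(mask[, cols] > 0)) "drop" else "keep"
}

#' Center, crop and pad an image to a uniform shape
#'
#' Crops to the smallest bounding box containing the foreground, then pads
#' symmetrically with black pixels to exactly `target_shape`, centering the
#' box; odd remainders put the extra pixel on the bottom/right.
#'
#' @param image H x W intensity matrix (masked; background 0).
#' @param target_shape `c(height, width)` of the output (default the
#'   200 x 794 standard).
#' @param mask optional binary mask; defaults to `image > 0` or the image's
#'   `foreground` attribute if present.
#' @return matrix of exactly `target_shape`, with updated `foreground`
#'   attribute.
#' @export
spatial_normalize <- function(image, target_shape = c(200L, 794L), mask = NULL) {
  fg <- if (!is.null(mask)) mask > 0 else attr(image, "foreground") %||% (image > 0)
  if (!any(fg)) stop("empty foreground")
  rr <- range(which(rowSums(fg) > 0))
  cc <- range(which(colSums(fg) > 0))
  h <- rr[2] - rr[1] + 1L
  w <- cc[2] - cc[1] + 1L
  if (h > target_shape[1] || w > target_shape[2]) {
    stop("oversize foreground: bounding box ", h, "x", w,
         " exceeds target ", target_shape[1], "x", target_shape[2])
  }
  crop <- image[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  crop_fg <- fg[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  top <- (target_shape[1] - h) %/% 2L
  left <- (target_shape[2] - w) %/% 2L
  out <- matrix(0, target_shape[1], target_shape[2])
  ofg <- matrix(FALSE, target_shape[1], target_shape[2])
  out[top + seq_len(h), left + seq_len(w)] <- crop
  ofg[top + seq_len(h), left + seq_len(w)] <- crop_fg
  attr(out, "foreground") <- ofg
  out
}

#' Invert foreground intensities, keeping the background black
#'
#' Foreground pixel v becomes `max_range - v`; background pixels stay at the
#' range minimum. Applying the operation twice restores the original image.
#'
#' @param image H x W intensity matrix.
#' @param max_range top of the intensity range (1 for normalized images,
#'   255 for 8-bit).
#' @param mask optional binary mask; defaults to the `foreground` attribute
#'   or `image > 0`.
#' @return inverted image with the `foreground` attribute preserved.
#' @export
invert_intensity <- function(image, max_range = 1, mask = NULL) {
  fg <- if (!is.null(mask)) mask > 0 else attr(image, "foreground") %||% (image > 0)
  image[fg] <- max_range - image[fg]
  attr(image, "foreground") <- fg
  image
}

#' Full preprocessing pass for one sample
#'
#' mask -> edge-truncation filter -> spatial normalization -> optional
#' intensity inversion. The geometric stages are idempotent; inversion is an
#' involution, so it is exposed as a flag rather than re-applied blindly.
#'
#' @param image H x W intensity matrix.
#' @param mask binary H x W mask.
#' @param target_shape output shape (default `c(200, 794)`).
#' @param boundary_px edge-filter band width.
#' @param invert apply [invert_intensity()] at the end.
#' @param max_range intensity range maximum.
#' @return list with `keep` (logical), `reason` (`"ok"` or `"edge"`), and
#'   `image` (the processed matrix, or NULL when dropped).
#' @export
preprocess_image <- function(image, mask, target_shape = c(200L, 794L),
                             boundary_px = 5L, invert = TRUE, max_range = 1) {
  img <- apply_mask(image, mask)
  if (edge_truncation_filter(mask, boundary_px) == "drop") {
    return(list(keep = FALSE, reason = "edge", image = NULL))
  }
  img <- spatial_normalize(img, target_shape, mask)
  if (invert) img <- invert_intensity(img, max_range)
  list(keep = TRUE, reason = "ok", image = img)
}

#' Preprocess a whole cohort with a QC report
#'
#' @param images named list of H x W matrices.
#' @param masks named list of binary masks (same names); if NULL, masks are
#'   thresholded from the images via [synthetic_mask()].
#' @param labels label table with a `sample_id` column.
#' @param ... passed to [preprocess_image()].
#' @return list with `images` (kept samples), `labels` (filtered table) and
#'   `qc` (data.frame: sample_id, kept, reason).
#' @export
preprocess_cohort <- function(images, masks = NULL, labels = NULL, ...) {
  ids <- names(images)
  if (is.null(masks)) masks <- lapply(images, synthetic_mask)
  out <- vector("list", length(ids)); names(out) <- ids
  kept <- logical(length(ids)); reason <- character(length(ids))
  for (i in seq_along(ids)) {
    r <- preprocess_image(images[[i]], masks[[ids[i]]], ...)
    kept[i] <- r$keep; reason[i] <- r$reason
    if (r$keep) out[[ids[i]]] <- r$image
  }
  qc <- data.frame(sample_id = ids, kept = kept, reason = reason,
                   stringsAsFactors = FALSE)
  out <- out[!vapply(out, is.null, logical(1))]
  if (!is.null(labels)) labels <- labels[labels$sample_id %in% names(out), , drop = FALSE]
  list(images = out, labels = labels, qc = qc)
}

#' Map a [0, max] image to the [-1, 1] model range (and back)
#'
#' @param image intensity matrix.
#' @param max_range intensity range maximum.
#' @return rescaled matrix.
#' @export
to_model_range <- function(image, max_range = 1) {
  image * (2 / max_range) - 1
}

#' @rdname to_model_range
#' @export
from_model_range <- function(image, max_range = 1) {
  (image + 1) * (max_range / 2)
}
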