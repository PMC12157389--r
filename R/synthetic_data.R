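# Synthetic cohort generator. Variation factorizes by construction:
# genotype -> silhouette geometry, clutch -> global intensity style,
# age -> isotropic scale. Intensities live in [0, 1]; background is 0.

#' Describe a synthetic multi-clutch cohort
#'
#' A cohort design fixes which genotypes are present in which clutch, the
#' number of images per (genotype, clutch, age) cell, the canvas size and
#' the effect sizes of the three latent factors. The control genotype must
#' be present in every clutch: controls raised alongside each clutch's
#' mutants are what later anchors the clutch-style estimates.
#'
#' @param genotypes character vector of genotype labels.
#' @param control control genotype label; must be in `genotypes` and in every
#'   clutch's assignment.
#' @param clutches character vector of clutch labels.
#' @param ages character vector of age labels, ordered youngest first
#'   (e.g. `c("3dpf", "5dpf")`).
#' @param assignment named list, clutch -> character vector of genotypes
#'   present in that clutch. Default: every genotype in every clutch.
#' @param n_per_group images per (genotype, clutch, age) cell.
#' @param image_shape canvas `c(height, width)` in pixels.
#' @param genotype_geometry_delta dimensionless multiplicative geometry
#'   perturbation distinguishing mutants from the control silhouette.
#' @param clutch_intensity_shift half-range of the per-clutch additive
#'   foreground intensity shift, as a fraction of the dynamic range. Clutch
#'   shifts are spread evenly over `[-shift, +shift]`.
#' @param clutch_noise_sigma sd of per-pixel additive foreground noise
#'   (intensity units).
#' @param age_scale_factor isotropic scale ratio between consecutive age
#'   groups (oldest = largest).
#' @param genotype_params optional named list of geometry overrides
#'   (as in [default_geometry()]) for specific genotypes; genotypes given
#'   identical entries are generated identically.
#' @param seed integer RNG seed; the whole cohort is reproducible from it.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(genotypes, control = genotypes[1], clutches, ages = c("3dpf", "5dpf"),
                          assignment = NULL, n_per_group = 40L,
                          image_shape = c(64L, 128L),
                          genotype_geometry_delta = 0.45,
                          clutch_intensity_shift = 0.30,
                          clutch_noise_sigma = 0.02,
                          age_scale_factor = 1.04,
                          genotype_params = NULL,
                          seed = 1L) {
  stopifnot(length(genotypes) >= 1, control %in% genotypes,
            length(clutches) >= 1, length(ages) >= 1,
            n_per_group >= 1, length(image_shape) == 2,
            image_shape[1] >= 32, image_shape[2] >= 32)
  if (is.null(assignment)) {
    assignment <- stats::setNames(rep(list(genotypes), length(clutches)), clutches)
  }
  if (!setequal(names(assignment), clutches)) {
    stop("assignment must have one entry per clutch")
  }
  if (length(assignment) == 0 || all(lengths(assignment) == 0)) {
    stop("empty assignment")
  }
  for (cl in clutches) {
    if (!control %in% assignment[[cl]]) {
      stop("control genotype '", control, "' missing from clutch '", cl, "'")
    }
    if (!all(assignment[[cl]] %in% genotypes)) stop("unknown genotype in assignment")
  }
  d <- list(genotypes = genotypes, control = control, clutches = clutches,
            ages = ages, assignment = assignment,
            n_per_group = as.integer(n_per_group),
            image_shape = as.integer(image_shape),
            genotype_geometry_delta = genotype_geometry_delta,
            clutch_intensity_shift = clutch_intensity_shift,
            clutch_noise_sigma = clutch_noise_sigma,
            age_scale_factor = age_scale_factor,
            genotype_params = genotype_params,
            seed = as.integer(seed))
  class(d) <- "cohort_design"
  d
}

#' Default silhouette geometry (the control body plan)
#'
#' Geometry parameters are fractions of the canvas: `body_len`/`body_height`
#' are the body-ellipse axes, `tail_len` the tapering-tail length,
#' `tail_height` the tail root height relative to the body half-height,
#' `intensity` the base foreground intensity and `jitter` the sd of the
#' per-individual multiplicative geometry perturbation.
#'
#' @return named list of geometry parameters.
#' @export
default_geometry <- function() {
  list(body_len = 0.22, body_height = 0.30, tail_len = 0.30,
       tail_height = 0.55, intensity = 0.60, jitter = 0.04)
}

# Deterministic genotype -> geometry map: mutants cycle through four distinct
# geometry perturbations of magnitude `delta`.
genotype_geometries <- function(design) {
  base <- default_geometry()
  d <- design$genotype_geometry_delta
  mods <- list(
    function(g, m) { g$tail_len <- g$tail_len * (1 + d * m); g },
    function(g, m) { g$tail_len <- g$tail_len * (1 - 0.9 * d * m); g },
    function(g, m) { g$body_height <- g$body_height * (1 + d * m); g },
    function(g, m) {
      g$body_height <- g$body_height * (1 - 0.8 * d * m)
      g$tail_len <- g$tail_len * (1 + 0.6 * d * m)
      g
    }
  )
  out <- list()
  mut_i <- 0L
  for (g in design$genotypes) {
    if (g == design$control) {
      out[[g]] <- base
    } else {
      mut_i <- mut_i + 1L
      k <- ((mut_i - 1L) %% 4L) + 1L
      m <- 1 + floor((mut_i - 1L) / 4L) * 0.5
      out[[g]] <- mods[[k]](base, m)
    }
  }
  for (g in names(design$genotype_params %||% list())) {
    out[[g]] <- utils::modifyList(out[[g]], design$genotype_params[[g]])
  }
  out
}

# Age label -> isotropic scale, youngest age = 1.0
age_scales <- function(design) {
  stats::setNames(design$age_scale_factor^(seq_along(design$ages) - 1), design$ages)
}

# Clutch label -> affine style: additive shift spread evenly over [-s, s]
# with an aligned contrast gain spread over [1 - s, 1 + s]. Styles are
# assigned mildest-first, so the earliest-listed clutches carry typical
# rather than extreme styles (as the control-richest clutch usually does
# in real cohorts).
style_units <- function(J) {
  if (J == 1) return(0)
  u <- 2 * (seq_len(J) - 1) / (J - 1) - 1
  u[order(abs(u), u)]
}

clutch_shifts <- function(design) {
  s <- design$clutch_intensity_shift
  stats::setNames(s * style_units(length(design$clutches)), design$clutches)
}

clutch_gains <- function(design) {
  s <- design$clutch_intensity_shift
  stats::setNames(1 + s * style_units(length(design$clutches)), design$clutches)
}

#' Render one synthetic organism silhouette
#'
#' Draws a single connected foreground object (ellipsoid body plus a
#' tapering tail) on a zero background. The silhouette is a deterministic
#' function of the geometry parameters, the age scale and the current RNG
#' state (which supplies the small per-individual jitter).
#'
#' @param geometry named list as returned by [default_geometry()].
#' @param age_scale isotropic scale multiplier.
#' @param canvas `c(height, width)`, both at least 32.
#' @return H x W intensity matrix in `[0, 1]`.
#' @export
render_individual <- function(geometry, age_scale = 1.0, canvas = c(64L, 128L)) {
  stopifnot(canvas[1] >= 32, canvas[2] >= 32, age_scale > 0)
  H <- canvas[1]; W <- canvas[2]
  jit <- geometry$jitter %||% 0
  # per-individual jitter: 4 multiplicative draws + 2 positional draws,
  # clamped at 2.5 sd so extreme draws cannot overflow the canvas
  clamp <- function(v, lim) pmin(pmax(v, -lim), lim)
  jmul <- exp(clamp(stats::rnorm(4, 0, jit), 2.5 * jit))
  jpos <- clamp(stats::rnorm(2, 0, jit), 2.5 * jit)
  a <- 0.5 * geometry$body_len * W * age_scale * jmul[1]
  b <- 0.5 * geometry$body_height * H * age_scale * jmul[2]
  Lt <- geometry$tail_len * W * age_scale * jmul[3]
  th <- geometry$tail_height * jmul[4]
  cx <- 0.24 * W + jpos[1] * W * 0.25
  cy <- 0.5 * H + jpos[2] * H * 0.25
  if (cx - a < 1 || cx + a + Lt > W - 1 || cy - b < 1 || cy + b > H - 1) {
    stop("silhouette overflow: geometry does not fit the canvas at scale ",
         signif(age_scale, 3))
  }
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), times = W), H, W)
  body <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
  # tail: half-height tapers linearly from th*b at the body centre to 0 at tip
  frac <- (xs - cx) / (a + Lt)
  hh <- b * th * (1 - frac)
  tail <- xs >= cx & frac <= 1 & abs(ys - cy) <= hh
  fg <- body | tail
  px <- matrix(0, H, W)
  if (any(fg)) {
    shade <- 1 - 0.25 * pmin(((ys - cy) / max(b, 1))^2, 1)
    px[fg] <- geometry$intensity * shade[fg]
  }
  px
}

#' Apply a clutch intensity style to an image
#'
#' Applies an affine intensity map `v -> gain * v + shift` plus i.i.d.
#' Gaussian noise to the foreground pixels only (foreground = nonzero
#' pixels), emulating batch-specific illumination/contrast differences; the
#' background is untouched and the result is clipped back to `[0, 1]`.
#'
#' @param pixels H x W intensity matrix in `[0, 1]`.
#' @param clutch_intensity_shift additive shift (fraction of dynamic range).
#' @param clutch_noise_sigma per-pixel noise sd.
#' @param clutch_contrast_gain multiplicative gain of the affine style map.
#' @return styled H x W matrix.
#' @export
inject_clutch_style <- function(pixels, clutch_intensity_shift = 0,
                                clutch_noise_sigma = 0,
                                clutch_contrast_gain = 1) {
  stopifnot(all(is.finite(pixels)), min(pixels) >= 0, max(pixels) <= 1)
  fg <- pixels > 0
  if (any(fg) && (clutch_intensity_shift != 0 || clutch_contrast_gain != 1)) {
    shifted <- clutch_contrast_gain * pixels[fg] + clutch_intensity_shift
    if (all(shifted > 1) || all(shifted < 0)) {
      stop("degenerate style: intensity shift maps the whole foreground out of range")
    }
    pixels[fg] <- shifted
  }
  if (any(fg) && clutch_noise_sigma > 0) {
    pixels[fg] <- pixels[fg] + stats::rnorm(sum(fg), 0, clutch_noise_sigma)
  }
  pmin(pmax(pixels, 0), 1)
}

#' Generate a labeled synthetic cohort
#'
#' Walks every (clutch, genotype, age) cell of the design and emits
#' `n_per_group` images whose geometry is set by genotype, style by clutch
#' and scale by age. Fully reproducible from `design$seed`.
#'
#' @param design a [cohort_design()].
#' @return list with `images` (named list of H x W matrices) and `labels`
#'   (data.frame: sample_id, genotype, clutch, age, control_flag).
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  geos <- genotype_geometries(design)
  scales <- age_scales(design)
  shifts <- clutch_shifts(design)
  gains <- clutch_gains(design)
  images <- list()
  rows <- list()
  for (cl in design$clutches) {
    for (g in design$assignment[[cl]]) {
      for (ag in design$ages) {
        for (i in seq_len(design$n_per_group)) {
          id <- sprintf("%s.%s.%s.%03d", cl, g, ag, i)
          px <- render_individual(geos[[g]], scales[[ag]], design$image_shape)
          px <- inject_clutch_style(px, shifts[[cl]], design$clutch_noise_sigma,
                                    gains[[cl]])
          images[[id]] <- px
          rows[[id]] <- data.frame(sample_id = id, genotype = g, clutch = cl,
                                   age = ag, control_flag = g == design$control,
                                   stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(images)) stop("empty assignment")
  labels <- do.call(rbind, rows)
  rownames(labels) <- NULL
  list(images = images, labels = labels)
}

#' Threshold segmentation mask for a synthetic image
#'
#' Synthetic images have an exactly-zero background, so foreground
#' segmentation reduces to thresholding at zero.
#'
#' @param image H x W intensity matrix.
#' @return binary H x W mask (1 = foreground) with attribute
#'   `source = "threshold-synthetic"`.
#' @export
synthetic_mask <- function(image) {
  m <- (image > 0) * 1L
  attr(m, "source") <- "threshold-synthetic"
  m
}
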