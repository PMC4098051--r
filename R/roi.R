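#' @keywords internal
"_PACKAGE"

# Subcategory -> default expected opacity count per ROI.  Profusion grades
# the areal concentration of small opacities, so counts per 5.6 mm ROI are
# sizeable for the small size classes and double per grade step.
.default_density <- c("0/0" = 0, "1/1" = 6, "2/2" = 12, "3/3" = 24)

# ILO size-class diameter ranges in mm (rounded opacities).  Irregular classes
# s/t are rendered as line elements and use pixel-scale defaults instead.
.diameter_ranges_mm <- list(
  p = c(0.7, 1.5),
  q = c(1.5, 3),
  r = c(3, 10)
)

.SUBCATEGORIES <- c("0/0", "1/1", "2/2", "3/3")
.SHAPE_SIZES <- c("p", "q", "r", "s", "t")

#' Configuration for one synthetic lung-texture ROI class
#'
#' Describes the statistical texture model of a region of interest (ROI):
#' a second-order polynomial background trend, correlated Gaussian noise,
#' optional vessel-like ridges, and (for abnormal subcategories) superimposed
#' small opacities.  Profusion subcategories follow the ILO convention
#' (`0/0` normal through `3/3` severe), shape/size classes are `p`, `q`, `r`
#' (rounded, increasing diameter) and `s`, `t` (irregular).
#'
#' @param roi_size ROI side length in pixels (square), at least 8.
#' @param pixel_mm Pixel spacing in millimetres.
#' @param subcategory Profusion subcategory, one of `"0/0"`, `"1/1"`,
#'   `"2/2"`, `"3/3"`.
#' @param shape_size Opacity shape/size class, one of `"p"`, `"q"`, `"r"`
#'   (rounded) or `"s"`, `"t"` (irregular).  Ignored for `"0/0"`.
#' @param opacity_density Expected number of opacities per ROI (Poisson mean).
#'   Defaults to 0 / 6 / 12 / 24 for subcategories 0/0 through 3/3.
#' @param opacity_diameter_mm Length-2 numeric range of opacity full width at
#'   half maximum in mm; defaults depend on `shape_size`.
#' @param contrast Peak opacity amplitude expressed as a multiple of the
#'   background noise standard deviation.
#' @param trend_coeffs Six coefficients `(c00, c10, c01, c20, c11, c02)` of
#'   the background surface `c00 + c10 x + c01 y + c20 x^2 + c11 xy + c02 y^2`
#'   over centred pixel coordinates.
#' @param noise_sd Standard deviation of the background noise (intensity
#'   units on the nominal 12-bit scale).
#' @param noise_correlation_px Gaussian correlation length of the background
#'   noise in pixels; 0 gives white noise.
#' @param ridge_amplitude Peak amplitude of vessel-like ridges; 0 disables.
#' @param n_ridges Number of ridges per ROI.
#' @param seed Integer RNG seed making the ROI reproducible.
#'
#' @return An object of class `texture_config`.
#' @export
texture_config <- function(roi_size = 32L,
                           pixel_mm = 0.175,
                           subcategory = "0/0",
                           shape_size = "q",
                           opacity_density = NULL,
                           opacity_diameter_mm = NULL,
                           contrast = 1.5,
                           trend_coeffs = c(2048, 1.5, -1, 0.02, 0.01, -0.015),
                           noise_sd = 30,
                           noise_correlation_px = 0.8,
                           ridge_amplitude = 40,
                           n_ridges = 1L,
                           seed = 1L) {
  subcategory <- match.arg(subcategory, .SUBCATEGORIES)
  shape_size <- match.arg(shape_size, .SHAPE_SIZES)
  stopifnot(
    length(roi_size) == 1, roi_size >= 8,
    length(pixel_mm) == 1, pixel_mm > 0,
    length(trend_coeffs) == 6, all(is.finite(trend_coeffs)),
    noise_sd >= 0, noise_correlation_px >= 0,
    contrast >= 0, n_ridges >= 0, ridge_amplitude >= 0
  )
  if (is.null(opacity_density)) {
    opacity_density <- unname(.default_density[subcategory])
  }
  if (subcategory == "0/0" && opacity_density != 0) {
    stop("subcategory 0/0 (normal) must have opacity_density 0")
  }
  if (is.null(opacity_diameter_mm)) {
    opacity_diameter_mm <- if (shape_size %in% names(.diameter_ranges_mm)) {
      .diameter_ranges_mm[[shape_size]]
    } else {
      c(NA_real_, NA_real_)  # irregular classes sized in pixels, not mm
    }
  }
  if (shape_size %in% c("p", "q", "r")) {
    if (min(opacity_diameter_mm) / pixel_mm < 1) {
      stop("opacity diameters must span at least one pixel at this spacing")
    }
  }
  structure(
    list(
      roi_size = as.integer(roi_size),
      pixel_mm = pixel_mm,
      subcategory = subcategory,
      shape_size = shape_size,
      opacity_density = opacity_density,
      opacity_diameter_mm = opacity_diameter_mm,
      contrast = contrast,
      trend_coeffs = as.numeric(trend_coeffs),
      noise_sd = noise_sd,
      noise_correlation_px = noise_correlation_px,
      ridge_amplitude = ridge_amplitude,
      n_ridges = as.integer(n_ridges),
      seed = as.integer(seed)
    ),
    class = "texture_config"
  )
}

#' Labelled region of interest
#'
#' The unit of analysis: a square grayscale intensity patch with its class
#' label and generating configuration.
#'
#' @param pixels Square numeric matrix of finite intensities.
#' @param label `"normal"` or `"abnormal"`; must agree with the
#'   configuration's subcategory (`normal` iff `0/0`).
#' @param config The [texture_config()] that produced (or describes) the ROI.
#' @param id Character identifier.
#'
#' @return An object of class `lung_roi`.
#' @export
labelled_roi <- function(pixels, label, config, id = "roi") {
  label <- match.arg(label, c("normal", "abnormal"))
  stopifnot(is.matrix(pixels), nrow(pixels) == ncol(pixels))
  if (!all(is.finite(pixels))) stop("ROI pixels must be finite")
  if ((label == "normal") != (config$subcategory == "0/0")) {
    stop("label 'normal' is only consistent with subcategory 0/0")
  }
  structure(
    list(pixels = pixels, label = label, config = config, id = id),
    class = "lung_roi"
  )
}

#' @export
print.lung_roi <- function(x, ...) {
  cat(sprintf(
    "<lung_roi %s> %dx%d px, %s (subcategory %s%s)\n",
    x$id, nrow(x$pixels), ncol(x$pixels), x$label, x$config$subcategory,
    if (x$label == "abnormal") paste0(", shape ", x$config$shape_size) else ""
  ))
  invisible(x)
}

#' @export
print.texture_config <- function(x, ...) {
  cat(sprintf(
    "<texture_config> %dx%d px @ %.3f mm, subcategory %s, shape %s, density %.1f, seed %d\n",
    x$roi_size, x$roi_size, x$pixel_mm, x$subcategory, x$shape_size,
    x$opacity_density, x$seed
  ))
  invisible(x)
}

# Evaluate with a temporary RNG state so generators are deterministic without
# disturbing the caller's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic derived seed < 2^31, mixing a master seed with an index.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 16807) %%
               2147483647)
}
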