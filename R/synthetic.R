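# Synthetic lung-texture generator.
#
# Emulates the texture statistics the classification scheme assumes: a smooth
# anatomical intensity trend (second-order polynomial), spatially correlated
# background noise (lung parenchyma mottle), occasional vessel-like ridges,
# and -- for abnormal classes -- superimposed small rounded opacities
# (isotropic Gaussian blobs, classes p/q/r) or irregular opacities (short
# random-walk line elements, classes s/t) at a Poisson-distributed count per
# ROI whose mean grows with the profusion subcategory.

# Background shared by normal and abnormal ROIs.  Draw order is fixed so that
# an abnormal ROI with density 0 reproduces the normal ROI bit for bit.
.gen_background <- function(config) {
  N <- config$roi_size
  half <- (N - 1) / 2
  x <- matrix(rep(seq(-half, half), each = N), N, N)   # column coordinate
  y <- matrix(rep(seq(-half, half), times = N), N, N)  # row coordinate
  cf <- config$trend_coeffs
  trend <- cf[1] + cf[2] * x + cf[3] * y + cf[4] * x^2 + cf[5] * x * y +
    cf[6] * y^2

  noise <- matrix(0, N, N)
  if (config$noise_sd > 0) {
    white <- matrix(stats::rnorm(N * N), N, N)
    if (config$noise_correlation_px > 0) {
      # Circular convolution with a Gaussian kernel normalised to unit
      # energy, so the smoothed field keeps exactly the requested SD.
      d <- c(0:(N %/% 2), -((N - (N %/% 2 + 1)):1))
      g <- exp(-d^2 / (2 * config$noise_correlation_px^2))
      k2 <- outer(g, g)
      k2 <- k2 / sqrt(sum(k2^2))
      noise <- Re(stats::fft(stats::fft(white) * stats::fft(k2),
                             inverse = TRUE)) / (N * N)
    } else {
      noise <- white
    }
    noise <- noise * config$noise_sd
  }

  ridges <- matrix(0, N, N)
  if (config$ridge_amplitude > 0 && config$n_ridges > 0) {
    for (i in seq_len(config$n_ridges)) {
      theta <- stats::runif(1, 0, pi)
      x0 <- stats::runif(1, -half, half)
      y0 <- stats::runif(1, -half, half)
      # vessels at this pixel scale are wide soft bands (FWHM well above the
      # opacity scale); the top-hat opening is what removes them downstream
      w <- stats::runif(1, 6, 10)
      # perpendicular distance to the line through (x0, y0) at angle theta
      dist <- abs(cos(theta) * (y - y0) - sin(theta) * (x - x0))
      ridges <- ridges + config$ridge_amplitude * exp(-dist^2 / (2 * w^2))
    }
  }

  trend + noise + ridges
}

# Stamp one rounded opacity (isotropic Gaussian blob) onto `img`.
.stamp_blob <- function(img, cx, cy, fwhm_px, amplitude) {
  N <- nrow(img)
  half <- (N - 1) / 2
  sigma <- fwhm_px / (2 * sqrt(2 * log(2)))
  x <- matrix(rep(seq(-half, half), each = N), N, N)
  y <- matrix(rep(seq(-half, half), times = N), N, N)
  img + amplitude * exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2))
}

# Stamp one irregular opacity: a random-walk polyline with Gaussian
# cross-profile.  Length 3-10 px, width 1-2 px (FWHM).
.stamp_segment <- function(img, cx, cy, len_px, width_px, amplitude) {
  N <- nrow(img)
  half <- (N - 1) / 2
  step <- 0.5
  n_pts <- max(2L, ceiling(len_px / step))
  ang <- stats::runif(1, 0, 2 * pi)
  px <- numeric(n_pts)
  py <- numeric(n_pts)
  px[1] <- cx
  py[1] <- cy
  for (i in 2:n_pts) {
    ang <- ang + stats::rnorm(1, 0, 0.35)  # direction jitter -> curvature
    px[i] <- px[i - 1] + step * cos(ang)
    py[i] <- py[i - 1] + step * sin(ang)
  }
  sigma <- width_px / (2 * sqrt(2 * log(2)))
  x <- matrix(rep(seq(-half, half), each = N), N, N)
  y <- matrix(rep(seq(-half, half), times = N), N, N)
  d2 <- matrix(Inf, N, N)
  for (i in seq_len(n_pts)) {
    d2 <- pmin(d2, (x - px[i])^2 + (y - py[i])^2)
  }
  img + amplitude * exp(-d2 / (2 * sigma^2))
}

.gen_opacities <- function(img, config) {
  n_op <- stats::rpois(1, config$opacity_density)
  if (n_op == 0) return(img)
  N <- nrow(img)
  half <- (N - 1) / 2
  amplitude <- config$contrast * max(config$noise_sd, 1)
  rounded <- config$shape_size %in% c("p", "q", "r")
  for (i in seq_len(n_op)) {
    cx <- stats::runif(1, -half, half)
    cy <- stats::runif(1, -half, half)
    if (rounded) {
      fwhm_mm <- stats::runif(1, config$opacity_diameter_mm[1],
                              config$opacity_diameter_mm[2])
      img <- .stamp_blob(img, cx, cy, fwhm_mm / config$pixel_mm, amplitude)
    } else {
      len <- stats::runif(1, 3, 10)
      width <- stats::runif(1, 1, 2)
      img <- .stamp_segment(img, cx, cy, len, width, amplitude)
    }
  }
  img
}

#' Generate a normal (subcategory 0/0) synthetic ROI
#'
#' Produces polynomial trend + correlated Gaussian noise + optional
#' vessel-like ridges.  Deterministic for a fixed `config$seed`.
#'
#' @param config A [texture_config()] with `subcategory = "0/0"`.
#' @param id Identifier stored on the ROI.
#' @return A [labelled_roi()] with label `"normal"`.
#' @export
#' @examples
#' roi <- gen_normal_roi(texture_config(seed = 7))
#' dim(roi$pixels)
gen_normal_roi <- function(config, id = "normal_roi") {
  stopifnot(inherits(config, "texture_config"))
  if (config$subcategory != "0/0") {
    stop("gen_normal_roi requires subcategory 0/0; got ", config$subcategory)
  }
  pixels <- with_seed(config$seed, .gen_background(config))
  labelled_roi(pixels, "normal", config, id)
}

#' Generate an abnormal synthetic ROI
#'
#' Normal background plus a Poisson-distributed number of opacities:
#' isotropic Gaussian blobs for rounded classes p/q/r (FWHM drawn from the
#' class diameter range) or short random-walk line elements for irregular
#' classes s/t.  With `opacity_density = 0` the pixel matrix equals the
#' normal background for the same seed.
#'
#' @param config A [texture_config()] with subcategory `"1/1"`, `"2/2"` or
#'   `"3/3"`.
#' @param id Identifier stored on the ROI.
#' @return A [labelled_roi()] with label `"abnormal"`.
#' @export
gen_abnormal_roi <- function(config, id = "abnormal_roi") {
  stopifnot(inherits(config, "texture_config"))
  if (config$subcategory == "0/0") {
    stop("gen_abnormal_roi requires an abnormal subcategory (1/1, 2/2, 3/3)")
  }
  pixels <- with_seed(config$seed, {
    bg <- .gen_background(config)
    .gen_opacities(bg, config)
  })
  labelled_roi(pixels, "abnormal", config, id)
}

#' Generate a labelled dataset of synthetic ROIs
#'
#' Generates `n_per_class` ROIs for every configuration, with a per-ROI RNG
#' stream derived from the master seed and the ROI index so the dataset is
#' reproducible and order-independent.
#'
#' @param configs List of [texture_config()] objects (one per class).
#' @param n_per_class Number of ROIs per configuration: a single count or a
#'   vector with one count per configuration, each at least 1.
#' @param seed Master seed.
#' @return An object of class `roi_dataset`: a list with `rois` (list of
#'   [labelled_roi()]) and `manifest` (data frame: id, label, subcategory,
#'   shape_size, seed).
#' @export
#' @examples
#' ds <- gen_dataset(list(texture_config(), texture_config(subcategory = "2/2")),
#'                   n_per_class = 3, seed = 1)
#' ds$manifest
gen_dataset <- function(configs, n_per_class, seed = 1L) {
  if (length(configs) == 0) stop("configs must be a non-empty list")
  if (length(n_per_class) == 1) {
    n_per_class <- rep(n_per_class, length(configs))
  }
  stopifnot(length(n_per_class) == length(configs), all(n_per_class >= 1))
  rois <- vector("list", sum(n_per_class))
  rows <- vector("list", length(rois))
  idx <- 0L
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    stopifnot(inherits(cfg, "texture_config"))
    for (k in seq_len(n_per_class[ci])) {
      idx <- idx + 1L
      roi_seed <- derive_seed(seed, idx)
      cfg_i <- cfg
      cfg_i$seed <- roi_seed
      id <- sprintf("roi_%04d_c%d_%s", idx,
                    match(cfg$subcategory, .SUBCATEGORIES) - 1L,
                    cfg$shape_size)
      roi <- if (cfg$subcategory == "0/0") {
        gen_normal_roi(cfg_i, id = id)
      } else {
        gen_abnormal_roi(cfg_i, id = id)
      }
      rois[[idx]] <- roi
      rows[[idx]] <- data.frame(
        id = id, label = roi$label, subcategory = cfg$subcategory,
        shape_size = cfg$shape_size, seed = roi_seed,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(rois = rois, manifest = do.call(rbind, rows), seed = as.integer(seed)),
    class = "roi_dataset"
  )
}

#' @export
print.roi_dataset <- function(x, ...) {
  cat(sprintf("<roi_dataset> %d ROIs (%d normal, %d abnormal), master seed %d\n",
              nrow(x$manifest), sum(x$manifest$label == "normal"),
              sum(x$manifest$label == "abnormal"), x$seed))
  invisible(x)
}

#' Write a dataset to disk as 16-bit PNGs plus a CSV manifest
#'
#' Intensities are stored on the nominal 12-bit scale (clamped to
#' \[0, 4095\] and written as 16-bit gray PNG).
#'
#' @param dataset A `roi_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "roi_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (roi in dataset$rois) {
    img <- pmin(pmax(roi$pixels / 4095, 0), 1)
    png::writePNG(img, file.path(dir, paste0(roi$id, ".png")))
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(dataset$manifest, path, row.names = FALSE)
  invisible(path)
}
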