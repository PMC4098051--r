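# Power-spectrum feature extraction.
#
# Each enhancement branch produces a square image whose centred 2-D power
# spectrum is scanned along quantised radial directions; the two directions
# with the largest aggregate spectral energy (main and second axes) supply
# the normalised feature profiles fed to the rule-based and ANN classifiers.

#' Centred 2-D power spectrum
#'
#' Squared magnitude of the unnormalised 2-D DFT, shifted so the zero
#' frequency sits at the centre bin (`floor(N/2) + 1`).  For real input the
#' spectrum is centrally symmetric.  The DC bin is never used as a feature.
#'
#' @param img An [enhanced_image()] or square numeric matrix.
#' @param pixel_mm Sampling interval of the source image in mm; `NA` for
#'   index-domain sources such as the GLCOM feature image.
#' @return An object of class `power_spectrum`: `matrix` (nonnegative,
#'   centred), `pixel_mm`, `source_branch`, `center` (index of DC bin).
#' @export
#' @examples
#' ps <- power_spectrum(matrix(rnorm(64), 8, 8))
#' ps$matrix[ps$center, ps$center]  # DC energy
power_spectrum <- function(img, pixel_mm = NA_real_) {
  branch <- if (inherits(img, "enhanced_image")) img$branch else "trend_only"
  m <- .enh_matrix(img)
  if (nrow(m) != ncol(m)) stop("power_spectrum requires a square matrix")
  if (!all(is.finite(m))) stop("input must be finite")
  N <- nrow(m)
  P <- Mod(stats::fft(m))^2
  shift <- c((N %/% 2 + 1):N, 1:(N %/% 2))
  P <- P[shift, shift]
  structure(
    list(matrix = P, pixel_mm = pixel_mm, source_branch = branch,
         center = N %/% 2 + 1),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %dx%d, source %s\n",
              nrow(x$matrix), ncol(x$matrix), x$source_branch))
  invisible(x)
}

#' Spatial frequency of a DFT bin
#'
#' `k / (N * pixel_mm)` cycles per millimetre for bin index `k` of an
#' `N`-sample record at `pixel_mm` spacing.  Bins 1 and 2 of a 32-pixel ROI
#' at 0.175 mm are the nodular-pattern frequencies used by the rule-based
#' classifier (0.179 and 0.357 cycles/mm).
#'
#' @param k Bin index (vectorised), `0 <= k <= N/2`.
#' @param N Record length in samples.
#' @param pixel_mm Sampling interval in millimetres.
#' @return Frequency in cycles/mm.
#' @export
#' @examples
#' round(bin_frequency(1:2, 32, 0.175), 3)  # 0.179, 0.357
bin_frequency <- function(k, N, pixel_mm) {
  stopifnot(N >= 2, pixel_mm > 0)
  if (any(k < 0) || any(k > N / 2)) stop("bin index must satisfy 0 <= k <= N/2")
  k / (N * pixel_mm)
}

# Quantised radial directions: angles from the centre to every lattice point
# on the boundary of the upper half spectrum, folded to [0, 180) degrees.
.axis_angles <- function(N) {
  half <- N %/% 2
  pts <- expand.grid(dx = -half:half, dy = 0:half)
  pts <- pts[pmax(abs(pts$dx), pts$dy) == half, ]
  ang <- atan2(pts$dy, pts$dx)
  ang <- ang %% pi  # fold 180 -> 0
  sort(unique(round(ang, 12)))
}

# Profile of PS values at integer radii 1..N/2 along direction `theta`,
# sampling the nearest lattice point; frequency offsets wrap modulo N
# (for even N the +N/2 offset aliases onto the -N/2 bin).
.axis_profile_values <- function(ps, theta) {
  N <- nrow(ps$matrix)
  half <- N %/% 2
  r <- seq_len(half)
  fx <- round(r * cos(theta))
  fy <- round(r * sin(theta))
  ix <- ((fx + half) %% N) + 1L  # shifted array: index = freq + half + 1
  iy <- ((fy + half) %% N) + 1L
  ps$matrix[cbind(iy, ix)]
}

#' Locate the main and second radial axes of a power spectrum
#'
#' Candidate radial lines are the quantised directions through the spectrum
#' centre (all directions to lattice points on the half-spectrum boundary,
#' folded to `[0, 180)` degrees).  Each line is scored by the sum of PS
#' values over its positive radial bins `1 ... N/2` (nearest-lattice
#' sampling; only the positive half is used since the spectrum is
#' symmetric).  The main axis maximises the score, the second axis is the
#' best remaining direction; ties go to the smaller angle.  A degenerate
#' all-zero spectrum yields zero profiles at 0 and 90 degrees.
#'
#' @param ps A [power_spectrum()].
#' @return List with `main` and `second`, each an `axis_profile`:
#'   `angle` (degrees in `[0, 180)`), `values` (length `N/2`), `rank`.
#' @export
find_axes <- function(ps) {
  stopifnot(inherits(ps, "power_spectrum"))
  angles <- .axis_angles(nrow(ps$matrix))
  profiles <- lapply(angles, function(a) .axis_profile_values(ps, a))
  scores <- vapply(profiles, sum, numeric(1))
  if (all(scores == 0)) {
    half <- nrow(ps$matrix) %/% 2
    zero <- numeric(half)
    return(list(
      main = structure(list(angle = 0, values = zero, rank = "main"),
                       class = "axis_profile"),
      second = structure(list(angle = 90, values = zero, rank = "second"),
                         class = "axis_profile")
    ))
  }
  i_main <- which.max(scores)            # first max = smallest angle on ties
  rest <- scores
  rest[i_main] <- -Inf
  i_second <- which.max(rest)
  list(
    main = structure(
      list(angle = angles[i_main] * 180 / pi, values = profiles[[i_main]],
           rank = "main"),
      class = "axis_profile"
    ),
    second = structure(
      list(angle = angles[i_second] * 180 / pi, values = profiles[[i_second]],
           rank = "second"),
      class = "axis_profile"
    )
  )
}

#' Normalise a PS profile
#'
#' Divides by `ref` (by default the profile's own maximum; in the feature
#' pipeline, the maximum over the concatenated main and second profiles), so
#' features lie in `[0, 1]` with branch maximum 1.  An all-zero profile is
#' returned unchanged with attribute `all_zero = TRUE` and a warning.
#'
#' @param values Nonnegative numeric vector.
#' @param ref Normalisation constant; defaults to `max(values)`.
#' @return Normalised vector.
#' @export
normalize_profile <- function(values, ref = max(values)) {
  stopifnot(all(values >= 0))
  if (ref == 0) {
    warning("all-zero profile; returned unchanged")
    attr(values, "all_zero") <- TRUE
    return(values)
  }
  values / ref
}

#' Branch parameters for feature extraction
#'
#' Fixes the enhancement settings used throughout a pipeline run.
#'
#' @param window_kind Window for the window branch (default `"hanning"`).
#' @param se_size Top-hat structuring element side (odd; default 21).
#' @param glcom_distance GLCOM displacement in pixels (default 2).
#' @param glcom_bits GLCOM gray-level depth (default 6).
#' @return An object of class `branch_params`.
#' @export
branch_params <- function(window_kind = "hanning", se_size = 21L,
                          glcom_distance = 2L, glcom_bits = 6L) {
  window_kind <- match.arg(window_kind, .WINDOW_KINDS)
  structure(list(window_kind = window_kind, se_size = as.integer(se_size),
                 glcom_distance = as.integer(glcom_distance),
                 glcom_bits = as.integer(glcom_bits)),
            class = "branch_params")
}

# One branch's normalised feature vector from a trend-corrected image:
# c(main profile, second profile) divided by the max over the pair.
.branch_features <- function(tc, branch, params, pixel_mm) {
  enh <- switch(branch,
    trend_only = tc,
    window = apply_window(tc, params$window_kind),
    tophat = top_hat(tc, params$se_size),
    glcom = glcom_image(quantize(tc, params$glcom_bits),
                        glcom_params(params$glcom_distance, params$glcom_bits))
  )
  ps <- power_spectrum(enh, pixel_mm = if (branch == "glcom") NA else pixel_mm)
  ax <- find_axes(ps)
  raw <- c(ax$main$values, ax$second$values)
  feat <- suppressWarnings(normalize_profile(raw, ref = max(raw)))
  attr(feat, "angles") <- c(main = ax$main$angle, second = ax$second$angle)
  feat
}

#' Build the power-spectrum feature vector of an ROI
#'
#' Runs trend correction, the requested enhancement branch, the power
#' spectrum, axis finding, and pair-max normalisation.  Branch vector
#' lengths: 32 for `trend_only`, `window` and `tophat` (16 bins on each of
#' the main and second axes), 64 for `glcom` (32 + 32 on the 64 x 64
#' feature image at 6-bit depth), and 128 for `combined`
#' (window, then top-hat, then GLCOM).
#'
#' @param roi A [labelled_roi()].
#' @param branch `"trend_only"`, `"window"`, `"tophat"`, `"glcom"` or
#'   `"combined"`.
#' @param params A [branch_params()].
#' @return Numeric feature vector in `[0, 1]` with attribute `angles`
#'   (per-branch main/second axis angles in degrees).
#' @export
#' @examples
#' roi <- gen_normal_roi(texture_config(seed = 2))
#' length(build_feature_vector(roi, "combined"))  # 128
build_feature_vector <- function(roi, branch = "combined",
                                 params = branch_params()) {
  branch <- match.arg(branch, c(.BRANCHES, "combined"))
  stopifnot(inherits(roi, "lung_roi"))
  tc <- trend_correct(roi)
  pm <- roi$config$pixel_mm
  if (branch != "combined") {
    return(.branch_features(tc, branch, params, pm))
  }
  w <- .branch_features(tc, "window", params, pm)
  t <- .branch_features(tc, "tophat", params, pm)
  g <- .branch_features(tc, "glcom", params, pm)
  feat <- c(w, t, g)
  attr(feat, "angles") <- rbind(window = attr(w, "angles"),
                                tophat = attr(t, "angles"),
                                glcom = attr(g, "angles"))
  feat
}

#' Extract feature matrices for a whole dataset
#'
#' Computes every branch's feature vector for every ROI (sharing the trend
#' correction), returning one matrix per method with ROIs in rows.
#'
#' @param dataset A `roi_dataset` from [gen_dataset()], or a list of
#'   [labelled_roi()].
#' @param params A [branch_params()].
#' @return An object of class `feature_set`: list with `features` (named
#'   list of matrices for `trend_only`, `window`, `tophat`, `glcom`,
#'   `combined`), `labels` (factor), `ids`.
#' @export
extract_features <- function(dataset, params = branch_params()) {
  rois <- if (inherits(dataset, "roi_dataset")) dataset$rois else dataset
  n <- length(rois)
  stopifnot(n >= 1)
  branches <- c("trend_only", "window", "tophat", "glcom")
  rows <- lapply(rois, function(roi) {
    tc <- trend_correct(roi)
    pm <- roi$config$pixel_mm
    lapply(stats::setNames(branches, branches), function(b) {
      as.numeric(.branch_features(tc, b, params, pm))
    })
  })
  features <- lapply(stats::setNames(branches, branches), function(b) {
    do.call(rbind, lapply(rows, `[[`, b))
  })
  features$combined <- cbind(features$window, features$tophat, features$glcom)
  labels <- factor(vapply(rois, `[[`, character(1), "label"),
                   levels = c("normal", "abnormal"))
  ids <- vapply(rois, `[[`, character(1), "id")
  for (b in names(features)) rownames(features[[b]]) <- ids
  structure(list(features = features, labels = labels, ids = ids,
                 params = params),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d ROIs; branch widths: %s\n",
              length(x$ids),
              paste(sprintf("%s=%d", names(x$features),
                            vapply(x$features, ncol, integer(1))),
                    collapse = ", ")))
  invisible(x)
}
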