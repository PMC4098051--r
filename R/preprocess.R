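# Trend correction: least-squares second-order polynomial surface removal.
#
# Chest-wall and gross-anatomy gradients dominate raw ROI intensities; a
# quadratic surface fitted over all pixels and subtracted leaves the texture
# component that the spectral features describe.

# Quadratic design matrix over centred pixel coordinates.  Centring keeps the
# normal equations well conditioned for small grids.
.poly2_design <- function(N) {
  half <- (N - 1) / 2
  x <- rep(seq(-half, half), each = N)   # column coordinate
  y <- rep(seq(-half, half), times = N)  # row coordinate
  cbind(c00 = 1, c10 = x, c01 = y, c20 = x^2, c11 = x * y, c02 = y^2)
}

.roi_matrix <- function(roi) {
  if (inherits(roi, "lung_roi")) roi$pixels
  else if (is.matrix(roi)) roi
  else stop("expected a lung_roi or a matrix")
}

#' Fit a second-order polynomial surface to an ROI
#'
#' Least-squares fit of
#' `f(x, y) = c00 + c10 x + c01 y + c20 x^2 + c11 xy + c02 y^2`
#' over all pixels, with centred pixel coordinates
#' `x, y in [-(N-1)/2, (N-1)/2]`.  Solved by QR via [stats::lm.fit()];
#' the design matrix is full rank on any grid with `N >= 3`.
#'
#' @param roi A [labelled_roi()] or a square numeric matrix.
#' @return A `trend_fit` list: `coeffs` (named length-6 vector),
#'   `residual_rms`, and `fitted` (the fitted surface as a matrix).
#' @export
fit_poly2_surface <- function(roi) {
  m <- .roi_matrix(roi)
  if (!all(is.finite(m))) stop("ROI pixels must be finite")
  N <- nrow(m)
  if (N * ncol(m) < 6) stop("need at least 6 pixels to fit 6 coefficients")
  X <- .poly2_design(N)
  fit <- stats::lm.fit(X, as.vector(m))
  coeffs <- fit$coefficients
  fitted <- matrix(X %*% coeffs, N, N)
  structure(
    list(
      coeffs = coeffs,
      residual_rms = sqrt(mean((m - fitted)^2)),
      fitted = fitted
    ),
    class = "trend_fit"
  )
}

#' Remove the fitted polynomial trend from an ROI
#'
#' Subtracts the least-squares quadratic surface pixelwise.  Because the
#' basis contains an intercept, the output has zero mean (to numerical
#' precision), and the operation is a linear projection: applying it twice
#' equals applying it once.
#'
#' @param roi A [labelled_roi()] or a square numeric matrix.
#' @return An [enhanced_image()] with branch `"trend_only"`.
#' @export
#' @examples
#' roi <- gen_normal_roi(texture_config(seed = 1))
#' tc <- trend_correct(roi)
#' abs(mean(tc$matrix)) < 1e-6
trend_correct <- function(roi) {
  m <- .roi_matrix(roi)
  fit <- fit_poly2_surface(m)
  enhanced_image(m - fit$fitted, branch = "trend_only",
                 params = list(coeffs = fit$coeffs))
}
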