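# Enhancement branches applied to trend-corrected ROIs:
#   1. radial window functions (Hanning / Hamming / Blackman) suppressing
#      spectral leakage from the ROI edge;
#   2. morphological top-hat transform (image minus opening with a flat
#      square structuring element) enhancing bright structures smaller than
#      the element;
#   3. gray-level co-occurrence matrix (GLCOM) feature image at directions
#      45 and 225 degrees, which is itself Fourier-transformed downstream.

.WINDOW_KINDS <- c("hanning", "hamming", "blackman")
.BRANCHES <- c("window", "tophat", "glcom", "trend_only")

#' Enhanced-image container
#'
#' Output of one enhancement branch (or of trend correction alone).
#'
#' @param matrix Square finite numeric matrix.
#' @param branch One of `"window"`, `"tophat"`, `"glcom"`, `"trend_only"`.
#' @param params List of branch parameters (recorded for provenance).
#' @return An object of class `enhanced_image`.
#' @export
enhanced_image <- function(matrix, branch, params = list()) {
  branch <- match.arg(branch, .BRANCHES)
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (!all(is.finite(matrix))) stop("enhanced image must be finite")
  if (branch %in% c("tophat", "glcom") && any(matrix < -1e-12)) {
    stop(branch, " branch matrix must be nonnegative")
  }
  structure(list(matrix = matrix, branch = branch, params = params),
            class = "enhanced_image")
}

#' @export
print.enhanced_image <- function(x, ...) {
  cat(sprintf("<enhanced_image> %dx%d, branch %s\n",
              nrow(x$matrix), ncol(x$matrix), x$branch))
  invisible(x)
}

.enh_matrix <- function(img) {
  if (inherits(img, "enhanced_image")) img$matrix
  else if (is.matrix(img)) img
  else stop("expected an enhanced_image or a matrix")
}

#' Radial window weight
#'
#' The three taper functions, evaluated at radial position `n` for a record
#' of `N` samples:
#' \deqn{H(n) = 0.5 + 0.5\cos(2\pi n/(N-1))}
#' \deqn{h(n) = 0.54 + 0.46\cos(2\pi n/(N-1))}
#' \deqn{B(n) = 0.42 + 0.5\cos(2\pi n/(N-1)) + 0.08\cos(4\pi n/(N-1))}
#' Valid radial positions are `|n| <= (N-1)/2`; beyond that (ROI corners
#' under the radial rule) `n` is clamped to `(N-1)/2`, giving the formula's
#' edge value and avoiding cosine wrap-around.
#'
#' @param kind `"hanning"`, `"hamming"` or `"blackman"`.
#' @param n Radial position(s); vectorised.
#' @param N Number of samples across the window, at least 2.
#' @return Numeric weights in `[0, 1]`.
#' @export
#' @examples
#' window_weight("hanning", 0, 32)            # 1
#' window_weight("hamming", (32 - 1) / 2, 32) # 0.08
window_weight <- function(kind, n, N) {
  kind <- match.arg(kind, .WINDOW_KINDS)
  if (length(N) != 1 || N < 2) stop("N must be a single value >= 2")
  half <- (N - 1) / 2
  n <- pmin(abs(n), half)
  a <- 2 * pi * n / (N - 1)
  w <- switch(kind,
    hanning  = 0.5 + 0.5 * cos(a),
    hamming  = 0.54 + 0.46 * cos(a),
    blackman = 0.42 + 0.5 * cos(a) + 0.08 * cos(2 * a)
  )
  pmin(pmax(w, 0), 1)  # shave float dust at the endpoints
}

#' Apply a radial window to a trend-corrected image
#'
#' Each pixel is multiplied by the window weight at its Euclidean distance
#' from the matrix centre, `n = sqrt(x^2 + y^2)` in centred pixel
#' coordinates, so the taper is radially symmetric and the ROI edge goes
#' smoothly to the window's edge value.
#'
#' @param img An [enhanced_image()] (branch `"trend_only"`) or matrix.
#' @param kind Window kind, see [window_weight()].
#' @return An [enhanced_image()] with branch `"window"`.
#' @export
apply_window <- function(img, kind = "hanning") {
  kind <- match.arg(kind, .WINDOW_KINDS)
  m <- .enh_matrix(img)
  N <- nrow(m)
  half <- (N - 1) / 2
  x <- matrix(rep(seq(-half, half), each = N), N, N)
  y <- matrix(rep(seq(-half, half), times = N), N, N)
  w <- window_weight(kind, sqrt(x^2 + y^2), N)
  enhanced_image(m * w, branch = "window", params = list(kind = kind))
}

# Sliding min/max filter of odd width k along rows or columns with
# edge replication; a flat square structuring element separates into a
# row pass and a column pass.
.slide <- function(m, k, fun, margin) {
  N <- if (margin == 1) nrow(m) else ncol(m)
  p <- (k - 1) %/% 2
  acc <- m
  for (o in setdiff(seq(-p, p), 0)) {
    idx <- pmin(pmax(seq_len(N) + o, 1), N)
    acc <- if (margin == 1) fun(acc, m[idx, , drop = FALSE])
           else fun(acc, m[, idx, drop = FALSE])
  }
  acc
}

.erode <- function(m, k) .slide(.slide(m, k, pmin, 1), k, pmin, 2)
.dilate <- function(m, k) .slide(.slide(m, k, pmax, 1), k, pmax, 2)

#' Grayscale morphological opening with a flat square structuring element
#'
#' Erosion followed by dilation, both with a `se_size` x `se_size` flat
#' square element; image borders are handled by edge replication.
#'
#' @param img An [enhanced_image()] or matrix.
#' @param se_size Odd structuring-element side length, `>= 3` and at most
#'   the image size.
#' @return A numeric matrix (same size as the input).
#' @export
opening <- function(img, se_size) {
  m <- .enh_matrix(img)
  if (length(se_size) != 1 || se_size %% 2 != 1) {
    stop("se_size must be a single odd integer (element needs a centre)")
  }
  if (se_size < 3 || se_size > nrow(m)) {
    stop("se_size must be >= 3 and <= the image size")
  }
  .dilate(.erode(m, se_size), se_size)
}

#' Morphological top-hat transform
#'
#' The trend-corrected image minus its opening.  Bright structures smaller
#' than the structuring element (nodular and irregular opacities) survive;
#' larger structures such as big vessels are removed by the opening and
#' cancel in the subtraction.  Output is nonnegative by the anti-extensivity
#' of opening.
#'
#' @param img An [enhanced_image()] (branch `"trend_only"`) or matrix.
#' @param se_size Odd structuring-element side, conventionally 13 to 25
#'   pixels for 32x32 ROIs.
#' @return An [enhanced_image()] with branch `"tophat"`.
#' @export
top_hat <- function(img, se_size = 21) {
  m <- .enh_matrix(img)
  th <- m - opening(m, se_size)
  th[th < 0] <- 0  # clip numerical dust; opening <= image analytically
  enhanced_image(th, branch = "tophat", params = list(se_size = se_size))
}

#' Linear min-max quantisation
#'
#' Rescales an image linearly to integers `0 ... 2^bits - 1` with
#' equal-width bins anchored at the per-image minimum and maximum.  A
#' constant image maps to all zeros.
#'
#' @param img An [enhanced_image()] or matrix.
#' @param bits Gray-level depth, 4 to 12.
#' @return Integer-valued matrix in `[0, 2^bits - 1]`.
#' @export
quantize <- function(img, bits = 6) {
  if (bits < 4 || bits > 12) stop("bits must be between 4 and 12")
  m <- .enh_matrix(img)
  L <- 2^bits
  rng <- max(m) - min(m)
  if (rng == 0) return(matrix(0, nrow(m), ncol(m)))
  q <- floor((m - min(m)) / rng * L)
  q[q == L] <- L - 1
  q
}

#' GLCOM parameters
#'
#' @param distance_px Pair displacement in pixels, `>= 1` (1 to 3 in typical
#'   use).
#' @param bits Gray-level depth of the quantised input, 4 to 12 (default 6).
#' @return An object of class `glcom_params`.  The direction set is fixed at
#'   \{45, 225\} degrees.
#' @export
glcom_params <- function(distance_px = 1L, bits = 6L) {
  stopifnot(distance_px >= 1, bits >= 4, bits <= 12)
  structure(list(distance_px = as.integer(distance_px),
                 directions = c(45, 225), bits = as.integer(bits)),
            class = "glcom_params")
}

#' Gray-level co-occurrence matrix feature image
#'
#' Joint probability of gray-level pairs `(i, j)` at displacement
#' `distance_px` along 45 degrees, accumulated over both opposite
#' directions (45 and 225 degrees), which makes the matrix symmetric, and
#' normalised to sum to 1.  The resulting `2^bits` x `2^bits` matrix is the
#' feature image passed to the spectral stage.
#'
#' @param q Integer-valued matrix in `[0, 2^bits)`, e.g. from [quantize()].
#' @param params A [glcom_params()].
#' @return An [enhanced_image()] with branch `"glcom"`.
#' @export
glcom_image <- function(q, params = glcom_params()) {
  q <- .enh_matrix(q)
  L <- 2^params$bits
  d <- params$distance_px
  N <- nrow(q)
  if (d >= N) stop("displacement must be smaller than the image size")
  if (any(q != floor(q)) || min(q) < 0 || max(q) >= L) {
    stop("q must be integer-valued in [0, 2^bits)")
  }
  # 45-degree pairs in centred Cartesian terms (x right, y up): partner of
  # pixel (row r, col c) is (row r - d, col c + d).
  a <- q[(d + 1):N, 1:(N - d)]
  b <- q[1:(N - d), (d + 1):N]
  tb <- table(factor(a, levels = 0:(L - 1)), factor(b, levels = 0:(L - 1)))
  M <- unclass(tb) + t(unclass(tb))  # 225 degrees = reversed pairs
  dimnames(M) <- NULL
  M <- M / sum(M)
  enhanced_image(M, branch = "glcom",
                 params = list(distance_px = d, bits = params$bits))
}
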