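# --- window functions -------------------------------------------------------

test_that("window weights hit their formula endpoints", {
  N <- 32
  edge <- (N - 1) / 2
  expect_equal(window_weight("hanning", 0, N), 1.0)
  expect_equal(window_weight("hanning", edge, N), 0.0, tolerance = 1e-12)
  expect_equal(window_weight("hamming", edge, N), 0.08, tolerance = 1e-12)
  expect_equal(window_weight("blackman", 0, N), 1.0)
  expect_equal(window_weight("blackman", edge, N), 0.0, tolerance = 1e-12)
  expect_error(window_weight("hanning", 0, 1), "N")
})

test_that("weights stay in [0,1], are clamped at corners, peak at centre", {
  N <- 32
  r <- seq(0, sqrt(2) * (N - 1) / 2, length.out = 200)  # out to the corner
  for (kind in c("hanning", "hamming", "blackman")) {
    w <- window_weight(kind, r, N)
    expect_true(all(w >= 0 & w <= 1))
    expect_equal(max(w), window_weight(kind, 0, N))
    # beyond the inscribed circle the weight sticks at the edge value
    expect_equal(window_weight(kind, 40, N),
                 window_weight(kind, (N - 1) / 2, N))
  }
})

test_that("pointwise weight ordering blackman <= hanning <= hamming", {
  r <- seq(0, 15.5, by = 0.1)
  wb <- window_weight("blackman", r, 32)
  wn <- window_weight("hanning", r, 32)
  wm <- window_weight("hamming", r, 32)
  expect_true(all(wb <= wn + 1e-12))
  expect_true(all(wn <= wm + 1e-12))
})

test_that("apply_window is radial: centre 1, edge midpoints 0 for hanning", {
  m <- matrix(1, 33, 33)
  out <- apply_window(m, "hanning")$matrix
  expect_equal(out[17, 17], 1.0)
  expect_lt(abs(out[17, 33]), 1e-12)
  expect_lt(abs(out[1, 17]), 1e-12)
  # radial symmetry
  expect_equal(out, out[33:1, ], tolerance = 1e-12)
  expect_equal(out, t(out), tolerance = 1e-12)
})

test_that("windowing removes axis-aligned spectral lines from an edge step", {
  # constant-plus-step toy image: sharp edge -> energy smeared along u,v axes
  m <- matrix(1, 32, 32)
  m[, 17:32] <- 5
  ps_raw <- power_spectrum(m)
  ps_win <- power_spectrum(apply_window(m, "hanning"))
  c0 <- ps_raw$center
  axis_energy <- function(P) {
    sum(P[c0, -c0]) + sum(P[-c0, c0])  # u,v axes excluding DC
  }
  expect_lt(axis_energy(ps_win$matrix), axis_energy(ps_raw$matrix))
})

# --- morphology -------------------------------------------------------------

test_that("opening leaves constants, removes lone peaks", {
  m <- matrix(4, 16, 16)
  expect_equal(opening(m, 3), m)
  m[8, 8] <- 100
  expect_equal(opening(m, 3), matrix(4, 16, 16))
  expect_error(opening(m, 4), "odd")
})

test_that("opening matches the brute-force sliding min/max oracle", {
  set.seed(21)
  for (k in c(3, 5)) {
    m <- matrix(rnorm(64), 8, 8)
    expect_equal(opening(m, k), oracle_opening(m, k))
  }
  m <- matrix(rnorm(32 * 32), 32, 32)
  expect_equal(opening(m, 13), oracle_opening(m, 13))
})

test_that("top-hat keeps small blobs, suppresses wide ridges", {
  N <- 32
  half <- (N - 1) / 2
  x <- matrix(rep(seq(-half, half), each = N), N, N)
  y <- matrix(rep(seq(-half, half), times = N), N, N)
  blob <- 10 * exp(-(x^2 + y^2) / (2 * (3 / 2.3548)^2))  # FWHM 3 px
  th_blob <- top_hat(blob, 13)$matrix
  expect_gte(max(th_blob), 0.9 * max(blob))
  # flat-topped vessel-like band, 20 px across: wider than the element,
  # so the opening reconstructs it and the top-hat removes it
  ridge <- 10 * (abs(x) <= 10)
  th_ridge <- top_hat(ridge, 13)$matrix
  expect_lte(max(th_ridge), 0.1 * max(ridge))
})

test_that("top-hat is nonnegative, zero on constants and openings", {
  expect_equal(top_hat(matrix(3, 16, 16), 5)$matrix, matrix(0, 16, 16))
  set.seed(6)
  m <- matrix(rnorm(1024, sd = 10), 32, 32)
  th <- top_hat(m, 15)$matrix
  expect_true(all(th >= 0))
  # opening is idempotent, so the top-hat of an opening is zero
  expect_equal(top_hat(opening(m, 15), 15)$matrix, matrix(0, 32, 32),
               tolerance = 1e-12)
})

test_that("retained top-hat energy grows with the structuring element", {
  set.seed(7)
  m <- matrix(rnorm(1024, sd = 10), 32, 32)
  sums <- vapply(c(13, 17, 21, 25), function(k) sum(top_hat(m, k)$matrix),
                 numeric(1))
  expect_true(all(diff(sums) >= 0))
})

# --- quantisation and GLCOM -------------------------------------------------

test_that("quantize maps min/max to bin extremes with equal-width bins", {
  m <- matrix(seq(-5, 5, length.out = 64), 8, 8)
  q6 <- quantize(m, 6)
  expect_equal(min(q6), 0)
  expect_equal(max(q6), 63)
  expect_equal(quantize(matrix(2, 4, 4), 6), matrix(0, 4, 4))
  # monotone ramp at 4 bits: 16 levels, equal occupancy by histogram oracle
  ramp <- matrix(seq(0, 1, length.out = 256), 16, 16)
  q4 <- quantize(ramp, 4)
  expect_equal(sort(unique(as.vector(q4))), 0:15)
  expect_true(all(tabulate(as.vector(q4) + 1, 16) == 16))
  expect_error(quantize(m, 3), "bits")
})

test_that("glcom matches the exhaustive pair-count oracle", {
  set.seed(31)
  bits <- 4
  q <- matrix(sample(0:15, 100, replace = TRUE), 10, 10)
  for (d in 1:3) {
    M <- glcom_image(q, glcom_params(d, bits))$matrix
    expect_equal(M, oracle_glcom(q, d, 16))
  }
  # 2x2 toy case, enumerable by hand through the oracle
  q2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(glcom_image(q2, glcom_params(1, 4))$matrix,
               oracle_glcom(q2, 1, 16))
})

test_that("glcom is a symmetric joint probability; constants concentrate", {
  set.seed(32)
  q <- matrix(sample(0:63, 32 * 32, replace = TRUE), 32, 32)
  M <- glcom_image(q, glcom_params(2, 6))$matrix
  expect_equal(sum(M), 1.0, tolerance = 1e-12)
  expect_equal(M, t(M))
  expect_true(all(M >= 0))

  Mc <- glcom_image(matrix(5, 8, 8), glcom_params(1, 6))$matrix
  expect_equal(Mc[6, 6], 1.0)
  expect_equal(sum(Mc), 1.0)

  expect_error(glcom_image(matrix(0, 4, 4), glcom_params(4, 6)), "smaller")
  expect_error(glcom_image(matrix(0.5, 8, 8), glcom_params(1, 6)), "integer")
})
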