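# Independent brute-force oracles used to validate the implementation.
# Each one is written in the most literal style possible and shares no code
# with the package internals.

# Least-squares quadratic surface via explicit normal equations.
oracle_poly2_fit <- function(m) {
  N <- nrow(m)
  half <- (N - 1) / 2
  x <- rep(seq(-half, half), each = N)
  y <- rep(seq(-half, half), times = N)
  X <- cbind(1, x, y, x^2, x * y, y^2)
  solve(t(X) %*% X, t(X) %*% as.vector(m))[, 1]
}

# Grayscale opening: literal sliding-window min then max with clamped
# (edge-replicated) windows.
oracle_opening <- function(m, k) {
  N <- nrow(m)
  p <- (k - 1) / 2
  clamp <- function(i) pmin(pmax(i, 1), N)
  ero <- matrix(0, N, N)
  for (i in 1:N) for (j in 1:N) {
    ero[i, j] <- min(m[clamp((i - p):(i + p)), clamp((j - p):(j + p))])
  }
  dil <- matrix(0, N, N)
  for (i in 1:N) for (j in 1:N) {
    dil[i, j] <- max(ero[clamp((i - p):(i + p)), clamp((j - p):(j + p))])
  }
  dil
}

# GLCOM by exhaustive directed pair enumeration: for every pixel, look up
# the partner at (row - d, col + d) (45 deg, x right / y up) and at
# (row + d, col - d) (225 deg); count into an L x L matrix; normalise.
oracle_glcom <- function(q, d, L) {
  N <- nrow(q)
  M <- matrix(0, L, L)
  for (r in 1:N) for (c in 1:N) {
    r2 <- r - d; c2 <- c + d
    if (r2 >= 1 && r2 <= N && c2 >= 1 && c2 <= N) {
      M[q[r, c] + 1, q[r2, c2] + 1] <- M[q[r, c] + 1, q[r2, c2] + 1] + 1
    }
    r3 <- r + d; c3 <- c - d
    if (r3 >= 1 && r3 <= N && c3 >= 1 && c3 <= N) {
      M[q[r, c] + 1, q[r3, c3] + 1] <- M[q[r, c] + 1, q[r3, c3] + 1] + 1
    }
  }
  M / sum(M)
}

# AUC as the exhaustive Mann-Whitney pairwise comparison with half credit
# for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "abnormal"]
  neg <- scores[labels == "normal"]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Matrix-free ANN forward pass: explicit loops over units.
oracle_ann_forward <- function(model, feature) {
  sig <- function(z) 1 / (1 + exp(-z))
  h <- numeric(model$arch["hidden"])
  for (j in seq_along(h)) {
    acc <- model$b1[j]
    for (i in seq_along(feature)) acc <- acc + feature[i] * model$W1[i, j]
    h[j] <- sig(acc)
  }
  acc <- model$b2[1]
  for (j in seq_along(h)) acc <- acc + h[j] * model$W2[j, 1]
  sig(acc)
}

# Exhaustive radial-axis scorer: same angle set contract as the package
# (lattice points on the half-spectrum boundary, folded to [0, 180)), but
# scored with naive loops.
oracle_axis_scores <- function(P) {
  N <- nrow(P)
  half <- N %/% 2
  angs <- c()
  for (dx in -half:half) for (dy in 0:half) {
    if (max(abs(dx), dy) == half) angs <- c(angs, atan2(dy, dx) %% pi)
  }
  angs <- sort(unique(round(angs, 12)))
  scores <- numeric(length(angs))
  for (ai in seq_along(angs)) {
    s <- 0
    for (r in 1:half) {
      fx <- round(r * cos(angs[ai]))
      fy <- round(r * sin(angs[ai]))
      ix <- ((fx + half) %% N) + 1
      iy <- ((fy + half) %% N) + 1
      s <- s + P[iy, ix]
    }
    scores[ai] <- s
  }
  list(angles = angs, scores = scores)
}

# Small labelled feature set with a known separable structure, for
# classifier tests.
make_separable_features <- function(n_per_class = 20, d = 2, gap = 3,
                                    seed = 42) {
  set.seed(seed)
  X <- rbind(
    matrix(stats::rnorm(n_per_class * d, mean = 0), ncol = d),
    matrix(stats::rnorm(n_per_class * d, mean = gap), ncol = d)
  )
  labels <- rep(c("normal", "abnormal"), each = n_per_class)
  list(X = X, labels = labels)
}
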