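# Rule-based plus ANN classification.
#
# The rule-based stage thresholds the normalised PS features at the two
# nodular-pattern frequency bins (0.179 and 0.357 cycles/mm for 32-px ROIs):
# a test ROI whose value at either bin exceeds the highest value seen among
# training normals is "obviously abnormal"; one below the lowest training
# abnormal at both bins is "obviously normal".  Everything else goes to a
# three-layer perceptron trained to 0.1 (normal) / 0.9 (abnormal) targets.
# With three enhancement branches the rule votes combine by logical OR, and
# the undecided remainder is scored by a 128-input combined ANN.

.RULE_DECISIONS <- c("obviously_abnormal", "obviously_normal", "undecided")

#' Learn rule-based thresholds from training features
#'
#' For each of the first two frequency bins of the main-axis profile
#' (feature columns 1 and 2), records the maximum over training normals and
#' the minimum over training abnormals.
#'
#' @param features Numeric matrix, ROIs in rows; columns 1 and 2 are the
#'   main-axis bins at the nodular-pattern frequencies.
#' @param labels Factor or character vector, `"normal"` / `"abnormal"`.
#' @return An object of class `rule_thresholds`: `max_normal` and
#'   `min_abnormal`, each length 2.
#' @export
learn_rule_thresholds <- function(features, labels) {
  stopifnot(is.matrix(features), ncol(features) >= 2,
            nrow(features) == length(labels))
  labels <- as.character(labels)
  if (!any(labels == "normal") || !any(labels == "abnormal")) {
    stop("training set must contain both classes")
  }
  norm <- features[labels == "normal", 1:2, drop = FALSE]
  abn <- features[labels == "abnormal", 1:2, drop = FALSE]
  structure(
    list(max_normal = apply(norm, 2, max),
         min_abnormal = apply(abn, 2, min)),
    class = "rule_thresholds"
  )
}

#' Apply the rule-based classifier to one feature vector
#'
#' `obviously_abnormal` if the value at either bin exceeds the training
#' normals' maximum; `obviously_normal` if the values at both bins fall
#' below the training abnormals' minimum; otherwise `undecided`.
#'
#' @param feature Numeric feature vector (columns 1 and 2 are used).
#' @param thresholds A [learn_rule_thresholds()] result.
#' @return One of `"obviously_abnormal"`, `"obviously_normal"`,
#'   `"undecided"`.
#' @export
rule_classify <- function(feature, thresholds) {
  stopifnot(inherits(thresholds, "rule_thresholds"), length(feature) >= 2)
  v <- feature[1:2]
  if (any(v > thresholds$max_normal)) "obviously_abnormal"
  else if (all(v < thresholds$min_abnormal)) "obviously_normal"
  else "undecided"
}

#' ANN training hyperparameters
#'
#' @param learning_rate Per-pattern gradient step size (default 0.05).
#' @param momentum Momentum coefficient (default 0.9).
#' @param epochs Passes over the training set (default 100).
#' @param init_range Weights initialised uniform(-`init_range`,
#'   `init_range`) (default 0.5).
#' @param seed RNG seed for weight initialisation.
#' @return An object of class `ann_hyper`.
#' @export
ann_hyper <- function(learning_rate = 0.05, momentum = 0.9, epochs = 100L,
                      init_range = 0.5, seed = 1L) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1, epochs >= 1,
            init_range > 0)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs), init_range = init_range,
                 seed = as.integer(seed)),
            class = "ann_hyper")
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train a three-layer perceptron
#'
#' Fully connected network with one sigmoid hidden layer and a single
#' sigmoid output, trained by classic per-pattern (online) backpropagation
#' with momentum on the squared error to targets 0.1 (normal) and 0.9
#' (abnormal), visiting training patterns in their stored order.
#' The canonical architectures are 32-17-1 (window / top-hat / trend-only
#' features), 64-33-1 (GLCOM) and 128-65-1 (combined); the default hidden
#' size `d/2 + 1` reproduces all three.
#'
#' @param features Numeric matrix, ROIs in rows.
#' @param labels `"normal"` / `"abnormal"` vector or factor.
#' @param hidden Hidden-layer size; default `ncol(features)/2 + 1`.
#' @param hyper An [ann_hyper()].
#' @return An object of class `ann_model`: weight matrices `W1` (d x h),
#'   `W2` (h x 1), biases `b1`, `b2`, `arch`, `hyper`, and
#'   `final_training_error` (mean squared error at the last epoch).
#' @export
train_ann <- function(features, labels, hidden = NULL,
                      hyper = ann_hyper()) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  labels <- as.character(labels)
  if (!any(labels == "normal") || !any(labels == "abnormal")) {
    stop("training set must contain both classes")
  }
  d <- ncol(features)
  h <- if (is.null(hidden)) as.integer(d / 2 + 1) else as.integer(hidden)
  n <- nrow(features)
  X <- features
  Tg <- matrix(ifelse(labels == "abnormal", 0.9, 0.1), n, 1)

  mom <- hyper$momentum
  lr <- hyper$learning_rate
  with_seed(hyper$seed, {
    W1 <- matrix(stats::runif(d * h, -hyper$init_range, hyper$init_range), d, h)
    b1 <- stats::runif(h, -hyper$init_range, hyper$init_range)
    W2 <- matrix(stats::runif(h, -hyper$init_range, hyper$init_range), h, 1)
    b2 <- stats::runif(1, -hyper$init_range, hyper$init_range)
    vW1 <- matrix(0, d, h); vb1 <- numeric(h)
    vW2 <- matrix(0, h, 1); vb2 <- 0
    for (ep in seq_len(hyper$epochs)) {
      for (i in seq_len(n)) {
        x <- X[i, ]
        hid <- .sigmoid(drop(x %*% W1) + b1)
        o <- .sigmoid(sum(hid * W2) + b2)
        delta_o <- (o - Tg[i]) * o * (1 - o)      # d(SE)/d(pre-activation)
        delta_h <- delta_o * W2[, 1] * hid * (1 - hid)
        vW2 <- mom * vW2 - lr * delta_o * hid
        vb2 <- mom * vb2 - lr * delta_o
        vW1 <- mom * vW1 - lr * outer(x, delta_h)
        vb1 <- mom * vb1 - lr * delta_h
        W2 <- W2 + vW2; b2 <- b2 + vb2
        W1 <- W1 + vW1; b1 <- b1 + vb1
      }
    }
    H <- .sigmoid(sweep(X %*% W1, 2, b1, `+`))
    O <- .sigmoid(H %*% W2 + b2[1])
    structure(
      list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
           arch = c(input = d, hidden = h, output = 1L),
           hyper = hyper, final_training_error = mean((O - Tg)^2)),
      class = "ann_model"
    )
  })
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("<ann_model> %d-%d-%d, final training MSE %.4g\n",
              x$arch["input"], x$arch["hidden"], x$arch["output"],
              x$final_training_error))
  invisible(x)
}

#' Score features with a trained ANN
#'
#' Deterministic forward pass; output in (0, 1), larger meaning more
#' abnormal.
#'
#' @param model An [train_ann()] model.
#' @param feature Numeric vector of length `arch["input"]`, or a matrix with
#'   that many columns (ROIs in rows).
#' @return Numeric score(s) in (0, 1).
#' @export
ann_score <- function(model, feature) {
  stopifnot(inherits(model, "ann_model"))
  X <- if (is.matrix(feature)) feature else matrix(feature, nrow = 1)
  if (ncol(X) != model$arch["input"]) {
    stop("feature length ", ncol(X), " does not match network input size ",
         model$arch["input"])
  }
  H <- .sigmoid(sweep(X %*% model$W1, 2, model$b1, `+`))
  as.numeric(.sigmoid(H %*% model$W2 + model$b2[1]))
}

#' Combine per-branch rule decisions by logical OR
#'
#' Any branch voting `obviously_abnormal` decides abnormal (abnormal
#' precedence minimises false negatives); otherwise any vote
#' `obviously_normal` decides normal; otherwise undecided.
#'
#' @param decisions Character vector of exactly three branch decisions.
#' @return A single rule decision.
#' @export
combined_rule <- function(decisions) {
  if (length(decisions) != 3 || !all(decisions %in% .RULE_DECISIONS)) {
    stop("expected exactly three valid branch decisions")
  }
  if (any(decisions == "obviously_abnormal")) "obviously_abnormal"
  else if (any(decisions == "obviously_normal")) "obviously_normal"
  else "undecided"
}

#' Trained combined classifier
#'
#' Bundles the per-branch rule thresholds and the combined 128-input ANN.
#'
#' @param thresholds Named list of [learn_rule_thresholds()] results for
#'   `window`, `tophat`, `glcom`.
#' @param model The combined [train_ann()] model (128 inputs).
#' @return An object of class `cad_model`.
#' @export
cad_model <- function(thresholds, model) {
  stopifnot(all(c("window", "tophat", "glcom") %in% names(thresholds)),
            inherits(model, "ann_model"))
  structure(list(thresholds = thresholds, model = model),
            class = "cad_model")
}

# Score one row of precomputed branch features.  `branch_rows` is a named
# list of numeric vectors (window, tophat, glcom); `combined_row` is their
# 128-element concatenation.
.cad_score_row <- function(branch_rows, combined_row, cad) {
  decisions <- vapply(c("window", "tophat", "glcom"), function(b) {
    rule_classify(branch_rows[[b]], cad$thresholds[[b]])
  }, character(1))
  fused <- combined_rule(decisions)
  if (fused == "obviously_abnormal") {
    list(value = 1.0, provenance = "rule_abnormal")
  } else if (fused == "obviously_normal") {
    list(value = 0.0, provenance = "rule_normal")
  } else {
    list(value = ann_score(cad$model, combined_row), provenance = "ann")
  }
}

#' Score an ROI with the combined rule-based plus ANN scheme
#'
#' Computes the three branch feature vectors, applies each branch's rule,
#' combines the votes by logical OR, and -- for undecided ROIs -- returns
#' the combined ANN output on the 128-element feature vector.  Rule-forced
#' decisions map to the extremes 1.0 (abnormal) and 0.0 (normal) so that
#' ROC ranking places them beyond every ANN score.
#'
#' @param roi A [labelled_roi()].
#' @param cad A [cad_model()].
#' @param params The [branch_params()] used in training.
#' @return A list of class `cad_score`: `value` in `[0, 1]` and
#'   `provenance` (`"rule_abnormal"`, `"rule_normal"` or `"ann"`).
#' @export
cad_score <- function(roi, cad, params = branch_params()) {
  stopifnot(inherits(roi, "lung_roi"), inherits(cad, "cad_model"))
  tc <- trend_correct(roi)
  pm <- roi$config$pixel_mm
  rows <- lapply(stats::setNames(c("window", "tophat", "glcom"),
                                 c("window", "tophat", "glcom")),
                 function(b) as.numeric(.branch_features(tc, b, params, pm)))
  out <- .cad_score_row(rows, c(rows$window, rows$tophat, rows$glcom), cad)
  structure(out, class = "cad_score")
}

#' @export
print.cad_score <- function(x, ...) {
  cat(sprintf("<cad_score> %.4f (%s)\n", x$value, x$provenance))
  invisible(x)
}
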