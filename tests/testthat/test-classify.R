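test_that("rule thresholds record class extrema at the two bins", {
  X <- rbind(c(0.1, 0.15), c(0.2, 0.25), c(0.5, 0.55), c(0.9, 0.95))
  lab <- c("normal", "normal", "abnormal", "abnormal")
  thr <- learn_rule_thresholds(X, lab)
  expect_equal(unname(thr$max_normal), c(0.2, 0.25))
  expect_equal(unname(thr$min_abnormal), c(0.5, 0.55))
  expect_error(learn_rule_thresholds(X, rep("normal", 4)), "both classes")

  # overlapping classes still yield well-defined thresholds
  X2 <- rbind(c(0.8, 0.8), c(0.3, 0.3))
  thr2 <- learn_rule_thresholds(X2, c("normal", "abnormal"))
  expect_gt(thr2$max_normal[1], thr2$min_abnormal[1])
})

test_that("rule decisions follow the either/both bin logic", {
  thr <- learn_rule_thresholds(
    rbind(c(0.2, 0.25), c(0.5, 0.55)), c("normal", "abnormal"))
  expect_equal(rule_classify(c(0.3, 0.1), thr), "obviously_abnormal")
  expect_equal(rule_classify(c(0.1, 0.3), thr), "obviously_abnormal")
  expect_equal(rule_classify(c(0.1, 0.1), thr), "obviously_normal")
  # undecided needs overlapping classes: between min_abnormal and max_normal
  thr_ov <- learn_rule_thresholds(
    rbind(c(0.6, 0.6), c(0.1, 0.1), c(0.4, 0.4), c(0.9, 0.9)),
    c("normal", "normal", "abnormal", "abnormal"))
  expect_equal(rule_classify(c(0.5, 0.5), thr_ov), "undecided")
})

test_that("training ROIs are never obviously mislabelled by the rule", {
  # by construction of the max/min thresholds
  set.seed(41)
  for (rep in 1:20) {
    X <- matrix(runif(40), 20, 2)
    lab <- sample(c("normal", "abnormal"), 20, replace = TRUE,
                  prob = c(0.5, 0.5))
    if (length(unique(lab)) < 2) next
    thr <- learn_rule_thresholds(X, lab)
    dec <- apply(X, 1, rule_classify, thresholds = thr)
    expect_false(any(dec == "obviously_abnormal" & lab == "normal"))
    expect_false(any(dec == "obviously_normal" & lab == "abnormal"))
  }
})

test_that("rule thresholds are untouched by test-set perturbations", {
  sep <- make_separable_features(15, d = 2)
  train <- 1:20
  thr1 <- learn_rule_thresholds(sep$X[train, ], sep$labels[train])
  X2 <- sep$X
  X2[-train, ] <- X2[-train, ] + 100  # perturb only held-out rows
  thr2 <- learn_rule_thresholds(X2[train, ], sep$labels[train])
  expect_identical(thr1, thr2)
})

test_that("the ANN separates linearly separable features perfectly", {
  sep <- make_separable_features(20, d = 2, gap = 3)
  model <- train_ann(sep$X, sep$labels, hidden = 3,
                     hyper = ann_hyper(epochs = 200, seed = 7))
  expect_equal(roc_auc(ann_score(model, sep$X), sep$labels), 1.0)
})

test_that("ANN training is seed-deterministic and outputs stay in (0,1)", {
  sep <- make_separable_features(10, d = 4, gap = 1)
  hy <- ann_hyper(epochs = 20, seed = 11)
  m1 <- train_ann(sep$X, sep$labels, hyper = hy)
  m2 <- train_ann(sep$X, sep$labels, hyper = hy)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  expect_equal(m1$arch, c(input = 4L, hidden = 3L, output = 1L))

  extreme <- rbind(rep(1e3, 4), rep(-1e3, 4), rnorm(4))
  s <- ann_score(m1, extreme)
  expect_true(all(s > 0 & s < 1))
  expect_error(ann_score(m1, rnorm(5)), "input size")
})

test_that("default hidden sizes follow the d/2 + 1 convention", {
  sep <- make_separable_features(5, d = 32, gap = 2)
  m <- train_ann(sep$X, sep$labels, hyper = ann_hyper(epochs = 1))
  expect_equal(unname(m$arch["hidden"]), 17L)
})

test_that("forward pass matches the loop-based oracle", {
  sep <- make_separable_features(8, d = 6, gap = 1)
  model <- train_ann(sep$X, sep$labels, hidden = 4,
                     hyper = ann_hyper(epochs = 10, seed = 3))
  for (i in c(1, 5, 16)) {
    expect_equal(ann_score(model, sep$X[i, ]),
                 oracle_ann_forward(model, sep$X[i, ]), tolerance = 1e-12)
  }
  # zero-weight model: score is exactly sigmoid(output bias)
  zero <- model
  zero$W1[] <- 0; zero$W2[] <- 0; zero$b1[] <- 0; zero$b2 <- 0.3
  expect_equal(ann_score(zero, sep$X[1, ]), 1 / (1 + exp(-0.3)))
})

test_that("score is monotone along an all-positive weight path", {
  sep <- make_separable_features(8, d = 3, gap = 1)
  model <- train_ann(sep$X, sep$labels, hidden = 2,
                     hyper = ann_hyper(epochs = 5, seed = 9))
  model$W1 <- abs(model$W1)
  model$W2 <- abs(model$W2)
  base <- c(0.1, 0.2, 0.3)
  scores <- vapply(seq(0, 2, by = 0.25), function(delta) {
    x <- base; x[2] <- x[2] + delta
    ann_score(model, x)
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("combined_rule implements OR with abnormal precedence", {
  expect_equal(
    combined_rule(c("undecided", "obviously_abnormal", "undecided")),
    "obviously_abnormal")
  expect_equal(combined_rule(rep("undecided", 3)), "undecided")
  expect_equal(
    combined_rule(c("obviously_normal", "obviously_abnormal", "undecided")),
    "obviously_abnormal")
  # exhaustive truth table over all 27 triples
  states <- c("obviously_abnormal", "obviously_normal", "undecided")
  for (a in states) for (b in states) for (c in states) {
    got <- combined_rule(c(a, b, c))
    want <- if (any(c(a, b, c) == "obviously_abnormal")) "obviously_abnormal"
            else if (any(c(a, b, c) == "obviously_normal")) "obviously_normal"
            else "undecided"
    expect_equal(got, want)
  }
  expect_error(combined_rule(c("undecided", "undecided")), "three")
})

test_that("cad_score fuses rules and ANN with extremal rule scores", {
  ds <- gen_study_dataset(10, seed = 23)
  fs <- extract_features(ds)
  lab <- as.character(fs$labels)
  thr <- lapply(
    stats::setNames(c("window", "tophat", "glcom"),
                    c("window", "tophat", "glcom")),
    function(b) learn_rule_thresholds(fs$features[[b]], lab))
  model <- train_ann(fs$features$combined, lab,
                     hyper = ann_hyper(epochs = 5, seed = 2))
  cad <- cad_model(thr, model)
  for (i in seq_along(ds$rois)) {
    sc <- cad_score(ds$rois[[i]], cad)
    expect_true(sc$value >= 0 && sc$value <= 1)
    if (sc$provenance == "rule_abnormal") expect_equal(sc$value, 1.0)
    if (sc$provenance == "rule_normal") expect_equal(sc$value, 0.0)
    if (sc$provenance == "ann") {
      expect_equal(sc$value,
                   ann_score(model, as.numeric(fs$features$combined[i, ])))
    }
  }
})
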