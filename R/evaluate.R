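# ROC evaluation protocol: repeated stratified halving into training and
# test sets, empirical ROC per split, vertical curve averaging, AUC mean
# +/- SD across splits, and two-tailed paired t tests between methods.

#' Create repeated stratified train/test halvings
#'
#' Each split randomly halves every class independently; odd class counts
#' give `ceiling(n/2)` training and `floor(n/2)` test ROIs (e.g. 117
#' abnormal ROIs split 59 / 58).
#'
#' @param labels Class label per ROI (`"normal"` / `"abnormal"`), or a
#'   `roi_dataset` whose manifest supplies them.
#' @param n_splits Number of independent splits (default 10).
#' @param seed Master RNG seed.
#' @return An object of class `split_plan`: list `splits` of
#'   `list(train, test)` index vectors, plus `n_splits` and `seed`.
#' @export
make_splits <- function(labels, n_splits = 10L, seed = 1L) {
  if (inherits(labels, "roi_dataset")) labels <- labels$manifest$label
  labels <- as.character(labels)
  stopifnot(n_splits >= 1)
  classes <- unique(labels)
  if (any(table(labels) < 2)) stop("every class needs at least 2 ROIs")
  splits <- with_seed(seed, {
    lapply(seq_len(n_splits), function(s) {
      train <- integer(0)
      for (cl in classes) {
        idx <- which(labels == cl)
        n_train <- ceiling(length(idx) / 2)
        train <- c(train, sample(idx, n_train))
      }
      train <- sort(train)
      list(train = train, test = setdiff(seq_along(labels), train))
    })
  })
  structure(list(splits = splits, n_splits = as.integer(n_splits),
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Empirical ROC curve
#'
#' Sweeps the decision threshold over the distinct score values (ties
#' grouped), returning the false and true positive rates from (0, 0) to
#' (1, 1).  Larger scores mean more abnormal.
#'
#' @param scores Numeric scores.
#' @param labels `"normal"` / `"abnormal"` per score (abnormal = positive).
#' @return Data frame with columns `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  pos <- labels == "abnormal"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  # cumulative counts at each distinct threshold (end of each tie group)
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last_of_group]
  fp <- cumsum(!p)[last_of_group]
  data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
}

#' Area under the empirical ROC curve
#'
#' Trapezoidal area under [roc_curve()], which equals the Mann-Whitney
#' U statistic normalised by the number of abnormal-normal pairs, counting
#' ties as one half.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c("abnormal", "abnormal", "normal", "normal"))
roc_auc <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

#' Vertically average ROC curves
#'
#' Linearly interpolates every curve's TPR onto a fixed FPR grid and
#' averages pointwise (duplicate FPR values within a curve contribute their
#' upper envelope).
#'
#' @param curves List of `data.frame(fpr, tpr)` curves.
#' @param grid FPR grid (default `seq(0, 1, 0.01)`).
#' @return Data frame with columns `fpr`, `tpr` (the averaged curve).
#' @export
average_roc <- function(curves, grid = seq(0, 1, by = 0.01)) {
  stopifnot(length(curves) >= 1)
  tprs <- vapply(curves, function(rc) {
    stats::approx(rc$fpr, rc$tpr, xout = grid, ties = max, rule = 2)$y
  }, numeric(length(grid)))
  data.frame(fpr = grid, tpr = rowMeans(as.matrix(tprs)))
}

#' Two-tailed paired t test on per-split AUCs
#'
#' Standard paired t statistic on the differences with `n - 1` degrees of
#' freedom.  Degenerate cases follow a fixed contract: all-zero differences
#' give `t = 0, p = 1`; zero-variance nonzero-mean differences report a
#' below-machine-floor p with `degenerate = TRUE`.
#'
#' @param auc_a,auc_b Equal-length numeric vectors (paired by split).
#' @return List: `t`, `p`, `df`, `degenerate`.
#' @export
paired_t_test <- function(auc_a, auc_b) {
  stopifnot(length(auc_a) == length(auc_b), length(auc_a) >= 2)
  d <- auc_a - auc_b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, df = length(d) - 1, degenerate = FALSE))
    }
    return(list(t = sign(mean(d)) * Inf, p = .Machine$double.xmin,
                df = length(d) - 1, degenerate = TRUE))
  }
  ht <- stats::t.test(auc_a, auc_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), degenerate = FALSE)
}

# Train and score one method on one split of a feature_set.
# Single-branch methods: rule on the branch's own bins 1-2 + ANN on the
# branch features.  Combined: per-branch rules + OR + 128-input ANN.
.run_method_split <- function(method, fs, train, test, hyper) {
  labels <- as.character(fs$labels)
  if (method == "combined") {
    thr <- lapply(stats::setNames(c("window", "tophat", "glcom"),
                                  c("window", "tophat", "glcom")),
                  function(b) {
                    learn_rule_thresholds(
                      fs$features[[b]][train, , drop = FALSE], labels[train])
                  })
    model <- train_ann(fs$features$combined[train, , drop = FALSE],
                       labels[train], hyper = hyper)
    cad <- cad_model(thr, model)
    scores <- vapply(test, function(i) {
      rows <- lapply(stats::setNames(c("window", "tophat", "glcom"),
                                     c("window", "tophat", "glcom")),
                     function(b) fs$features[[b]][i, ])
      .cad_score_row(rows, fs$features$combined[i, ], cad)$value
    }, numeric(1))
  } else {
    X <- fs$features[[method]]
    thr <- learn_rule_thresholds(X[train, , drop = FALSE], labels[train])
    model <- train_ann(X[train, , drop = FALSE], labels[train], hyper = hyper)
    ann <- ann_score(model, X[test, , drop = FALSE])
    scores <- vapply(seq_along(test), function(j) {
      dec <- rule_classify(X[test[j], ], thr)
      switch(dec,
             obviously_abnormal = 1.0,
             obviously_normal = 0.0,
             undecided = ann[j])
    }, numeric(1))
  }
  scores
}

#' Run the full split/train/score/ROC experiment
#'
#' Extracts features once, then for every split trains every requested
#' method on the same training half and scores the same test half (the
#' paired design that licenses the paired t test).  Reports per-method AUC
#' mean +/- SD across splits, the vertically averaged ROC curve, and the
#' paired t test for every method pair.
#'
#' @param dataset A `roi_dataset`, or a precomputed `feature_set` from
#'   [extract_features()].
#' @param methods Subset of `"trend_only"`, `"window"`, `"tophat"`,
#'   `"glcom"`, `"combined"`.
#' @param n_splits Number of stratified halvings (default 10).
#' @param seed Master seed for the split plan and per-split ANN seeds.
#' @param params [branch_params()] used if features must be extracted.
#' @param hyper Base [ann_hyper()]; each (split, method) gets a seed derived
#'   from `seed`.
#' @return An object of class `experiment_result`: `roc` (per-method list
#'   with `auc` vector, `mean_auc`, `sd_auc`, `curve`), `pairwise`
#'   (data frame of paired t tests), `splits`, `methods`, `seed`.
#' @export
run_experiment <- function(dataset,
                           methods = c("trend_only", "combined"),
                           n_splits = 10L, seed = 1L,
                           params = branch_params(),
                           hyper = ann_hyper()) {
  methods <- match.arg(methods,
                       c("trend_only", "window", "tophat", "glcom", "combined"),
                       several.ok = TRUE)
  fs <- if (inherits(dataset, "feature_set")) dataset
        else extract_features(dataset, params)
  if (nlevels(droplevels(fs$labels)) < 2) stop("dataset needs both classes")
  plan <- make_splits(as.character(fs$labels), n_splits, seed)

  auc <- matrix(NA_real_, n_splits, length(methods),
                dimnames = list(NULL, methods))
  curves <- lapply(stats::setNames(methods, methods),
                   function(m) vector("list", n_splits))
  for (s in seq_len(n_splits)) {
    sp <- plan$splits[[s]]
    test_labels <- as.character(fs$labels)[sp$test]
    for (mi in seq_along(methods)) {
      m <- methods[mi]
      hy <- hyper
      hy$seed <- derive_seed(seed, s * 100 + mi)
      scores <- .run_method_split(m, fs, sp$train, sp$test, hy)
      auc[s, m] <- roc_auc(scores, test_labels)
      curves[[m]][[s]] <- roc_curve(scores, test_labels)
    }
  }

  roc <- lapply(stats::setNames(methods, methods), function(m) {
    list(auc = auc[, m], mean_auc = mean(auc[, m]),
         sd_auc = stats::sd(auc[, m]),
         curve = average_roc(curves[[m]]))
  })
  pairwise <- NULL
  if (length(methods) >= 2 && n_splits >= 2) {
    combos <- utils::combn(methods, 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
      a <- combos[1, i]; b <- combos[2, i]
      tt <- paired_t_test(auc[, a], auc[, b])
      data.frame(method_a = a, method_b = b, t = tt$t, p = tt$p,
                 df = tt$df, stringsAsFactors = FALSE)
    }))
  }
  structure(
    list(roc = roc, pairwise = pairwise, splits = plan,
         methods = methods, seed = as.integer(seed)),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d splits, seed %d\n",
              x$splits$n_splits, x$seed))
  for (m in x$methods) {
    cat(sprintf("  %-11s AUC %.3f +/- %.3f\n",
                m, x$roc[[m]]$mean_auc, x$roc[[m]]$sd_auc))
  }
  if (!is.null(x$pairwise)) {
    for (i in seq_len(nrow(x$pairwise))) {
      cat(sprintf("  %s vs %s: t = %.2f, p = %.3g\n",
                  x$pairwise$method_a[i], x$pairwise$method_b[i],
                  x$pairwise$t[i], x$pairwise$p[i]))
    }
  }
  invisible(x)
}
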