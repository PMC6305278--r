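# One-vs-rest random-forest classification of Gleason-score groups:
# stratified 5-fold cross-validation, balanced 40/20 hold-out validation,
# AUC/accuracy/NPV/PPV metrics, and normalized out-of-bag permutation
# importance.

#' Random-forest configuration
#'
#' @param n_trees trees per forest (default 500).
#' @param n_folds cross-validation folds (default 5); must not exceed the
#'   smallest class size.
#' @param seed master seed; fold assignment, per-fold forest fits and
#'   hold-out subset draws all derive their seeds from it by a fixed
#'   stream-splitting rule (one `sample.int()` draw per consumer), so every
#'   result is replayable.
#' @param mtry_rule per-split feature subsampling rule; `"sqrt"` (default,
#'   `floor(sqrt(p))` candidate features per split) or `"all"`.
#' @return An object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 500L, n_folds = 5L, seed = 1L,
                      mtry_rule = c("sqrt", "all")) {
  mtry_rule <- match.arg(mtry_rule)
  n_trees <- as.integer(n_trees)
  n_folds <- as.integer(n_folds)
  if (n_trees < 1L) stop("n_trees must be >= 1")
  if (n_folds < 2L) stop("n_folds must be >= 2")
  structure(list(n_trees = n_trees, n_folds = n_folds,
                 seed = as.integer(seed), mtry_rule = mtry_rule),
            class = "rf_config")
}

#' One-vs-rest binary labels
#'
#' @param groups vector of group labels.
#' @param target the positive group.
#' @return Integer vector: 1 for the target group, 0 otherwise.
#' @export
one_vs_rest_labels <- function(groups, target) {
  if (!target %in% groups) {
    stop("target group ", target, " is absent from the cohort")
  }
  if (all(groups == target)) {
    stop("target group ", target, " has no negatives in the cohort")
  }
  as.integer(groups == target)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney U probability that a randomly chosen
#' positive outscores a randomly chosen negative, with ties counted half —
#' equivalent to trapezoidal integration of the ROC curve.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels (0/1); both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: both classes must be present")
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' False-positive and true-positive rates at every distinct score threshold,
#' for plotting.
#'
#' @inheritParams roc_auc
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0,
                 numeric(1)),
    tpr = vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1,
                 numeric(1))
  )
}

# confusion-matrix metrics at a hard threshold; undefined ratios (empty
# denominator) are NA and excluded from fold averages
binary_metrics <- function(prob, labels, threshold = 0.5) {
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  list(auc = roc_auc(prob, labels),
       accuracy = (tp + tn) / length(labels),
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       confusion = matrix(c(tn, fn, fp, tp), 2, 2,
                          dimnames = list(truth = c("0", "1"),
                                          predicted = c("0", "1"))))
}

# stratified fold assignment: positives and negatives are shuffled
# separately and dealt round-robin, so fold sizes differ by <= 1 and every
# fold keeps both classes
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

fit_rf <- function(x, y, cfg) {
  mtry <- if (cfg$mtry_rule == "sqrt") max(1L, floor(sqrt(ncol(x)))) else ncol(x)
  randomForest::randomForest(x, factor(y, levels = c(0L, 1L)),
                             ntree = cfg$n_trees, mtry = mtry,
                             importance = TRUE, keep.forest = TRUE)
}

#' Cross-validated one-vs-rest random forest
#'
#' Stratified `cfg$n_folds`-fold cross-validation of a random forest for
#' one target group against the rest. Per fold the forest is fit on the
#' remaining folds and scored on the held-out fold; AUC, accuracy, NPV and
#' PPV are computed per fold and averaged, and out-of-fold hard predictions
#' at threshold 0.5 are pooled into one confusion matrix.
#'
#' @param tab a `feature_table`.
#' @param target the positive group label.
#' @param cfg an [rf_config()].
#' @return An object of class `rf_cv`: list with `task`, `fold_metrics`
#'   (per-fold data.frame), `mean_metrics`, `confusion`, `oof_scores`
#'   (out-of-fold probabilities per patient), `fold` assignment, and `fits`
#'   (the per-fold forests, retained for [permutation_importance()]).
#' @export
crossval_rf <- function(tab, target, cfg = rf_config()) {
  stopifnot(inherits(tab, "feature_table"))
  labels <- one_vs_rest_labels(tab$group, target)
  if (min(table(labels)) < cfg$n_folds) {
    stop("each class needs at least n_folds = ", cfg$n_folds,
         " members (have ", paste(table(labels), collapse = "/"), ")")
  }
  x <- feature_matrix(tab)

  set.seed(cfg$seed)
  fold <- stratified_folds(labels, cfg$n_folds)
  fold_seeds <- sample.int(2147483646L, cfg$n_folds)

  oof <- numeric(length(labels))
  fits <- vector("list", cfg$n_folds)
  fm <- vector("list", cfg$n_folds)
  for (k in seq_len(cfg$n_folds)) {
    test <- fold == k
    set.seed(fold_seeds[k])
    fit <- fit_rf(x[!test, , drop = FALSE], labels[!test], cfg)
    prob <- predict(fit, x[test, , drop = FALSE], type = "prob")[, "1"]
    oof[test] <- prob
    met <- binary_metrics(prob, labels[test])
    fm[[k]] <- data.frame(fold = k, auc = met$auc, accuracy = met$accuracy,
                          npv = met$npv, ppv = met$ppv)
    fits[[k]] <- fit
  }
  fold_metrics <- do.call(rbind, fm)
  pooled <- binary_metrics(oof, labels)

  structure(
    list(task = paste0("G", target, "-vs-rest"),
         target = target,
         fold_metrics = fold_metrics,
         mean_metrics = colMeans(fold_metrics[, c("auc", "accuracy",
                                                  "npv", "ppv")],
                                 na.rm = TRUE),
         confusion = pooled$confusion,
         oof_scores = stats::setNames(oof, tab$patient_id),
         labels = labels,
         fold = fold,
         fits = fits,
         cfg = cfg),
    class = "rf_cv"
  )
}

#' @export
print.rf_cv <- function(x, ...) {
  m <- x$mean_metrics
  cat(sprintf("<rf_cv> %s: %d-fold CV, %d trees\n", x$task,
              x$cfg$n_folds, x$cfg$n_trees))
  cat(sprintf("  mean AUC %.3f | accuracy %.3f | NPV %.3f | PPV %.3f\n",
              m["auc"], m["accuracy"], m["npv"], m["ppv"]))
  invisible(x)
}

#' Plot the out-of-fold ROC curve
#'
#' @param x an `rf_cv`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rf_cv <- function(x, ...) {
  pts <- roc_points(x$oof_scores, x$labels)
  graphics::plot(pts$fpr, pts$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("%s (out-of-fold AUC %.3f)", x$task,
                                roc_auc(x$oof_scores, x$labels)), ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  invisible(x)
}

#' Normalized out-of-bag permutation importance
#'
#' For each fold's forest, the per-tree increase in out-of-bag prediction
#' error after permuting one feature's values among that tree's out-of-bag
#' samples is averaged over trees and divided by its standard deviation
#' over trees (forests are fit with `importance = TRUE`, which performs
#' exactly this OOB permutation per tree); the per-fold normalized values
#' are then averaged across folds. Positive values mark predictive
#' features; values near or below zero mark features without predictive
#' value.
#'
#' @param cv an `rf_cv` from [crossval_rf()] (with retained fits).
#' @return Named numeric vector, one normalized importance per feature.
#' @export
permutation_importance <- function(cv) {
  stopifnot(inherits(cv, "rf_cv"))
  if (is.null(cv$fits) || !length(cv$fits)) {
    stop("cross-validation object does not retain fitted forests")
  }
  per_fold <- vapply(cv$fits, function(fit) {
    raw <- fit$importance[, "MeanDecreaseAccuracy"]
    sdv <- fit$importanceSD[, "MeanDecreaseAccuracy"]
    out <- ifelse(sdv > 0, raw / sdv, 0)
    out
  }, numeric(nrow(cv$fits[[1]]$importance)))
  rowMeans(per_fold)
}

#' Balanced hold-out validation
#'
#' Draws class-balanced, disjoint training (`n_train`, half positive) and
#' test (`n_test`, half positive) subsets, fits one forest on the training
#' subset and reports test-set AUC, accuracy, NPV and PPV. If the table is
#' unscaled, min-max scaling parameters are computed on the training subset
#' only and applied to the test subset (no leakage). Patients not drawn
#' into either subset are left unused and counted.
#'
#' @param tab a `feature_table`.
#' @param target the positive group label.
#' @param n_train training-set size (default 40).
#' @param n_test test-set size (default 20).
#' @param cfg an [rf_config()].
#' @param scale apply train-derived min-max scaling when the table is raw?
#' @return An object of class `rf_holdout`: metrics list plus the drawn ID
#'   sets, fitted forest, and unused-patient count.
#' @export
holdout_rf <- function(tab, target, n_train = 40L, n_test = 20L,
                       cfg = rf_config(), scale = TRUE) {
  stopifnot(inherits(tab, "feature_table"))
  labels <- one_vs_rest_labels(tab$group, target)
  ntr <- as.integer(n_train) %/% 2L
  nte <- as.integer(n_test) %/% 2L
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  need <- ntr + nte
  if (length(pos) < need || length(neg) < need) {
    stop("balanced hold-out needs ", need, " patients per class; have ",
         length(pos), " positives and ", length(neg), " negatives")
  }
  set.seed(cfg$seed)
  pos <- sample(pos); neg <- sample(neg)
  train_idx <- c(pos[seq_len(ntr)], neg[seq_len(ntr)])
  test_idx <- c(pos[ntr + seq_len(nte)], neg[ntr + seq_len(nte)])
  fit_seed <- sample.int(2147483646L, 1L)

  if (scale && !isTRUE(attr(tab, "scaled"))) {
    train_tab <- scale_features(tab[train_idx, ])
    test_tab <- scale_features(tab[test_idx, ],
                               params = attr(train_tab, "scaling"))
  } else {
    train_tab <- tab[train_idx, ]
    test_tab <- tab[test_idx, ]
  }
  set.seed(fit_seed)
  fit <- fit_rf(feature_matrix(train_tab), labels[train_idx], cfg)
  prob <- predict(fit, feature_matrix(test_tab), type = "prob")[, "1"]
  met <- binary_metrics(prob, labels[test_idx])

  structure(
    list(task = paste0("G", target, "-vs-rest"),
         target = target,
         metrics = met[c("auc", "accuracy", "npv", "ppv")],
         confusion = met$confusion,
         scores = stats::setNames(prob, tab$patient_id[test_idx]),
         train_ids = tab$patient_id[train_idx],
         test_ids = tab$patient_id[test_idx],
         n_unused = nrow(tab) - length(train_idx) - length(test_idx),
         fit = fit,
         cfg = cfg),
    class = "rf_holdout"
  )
}

#' @export
print.rf_holdout <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<rf_holdout> %s: train %d / test %d (%d unused)\n",
              x$task, length(x$train_ids), length(x$test_ids), x$n_unused))
  cat(sprintf("  AUC %.3f | accuracy %.3f | NPV %.3f | PPV %.3f\n",
              m$auc, m$accuracy, m$npv, m$ppv))
  invisible(x)
}

# subset method keeps feature_table attributes
#' @export
`[.feature_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("patient_id", "group") %in% names(out))) {
    attr(out, "scaled") <- attr(x, "scaled")
    attr(out, "scaling") <- attr(x, "scaling")
    class(out) <- c("feature_table", "data.frame")
  }
  out
}

#' Per-modality classification comparison
#'
#' Repeats the balanced hold-out classification for every one-vs-rest task
#' on each of the modality-specific feature tables (modality-averaged,
#' T2-only, ADC-only), mirroring the per-modality reruns of the analysis.
#' Tables must contain the same patients in the same order.
#'
#' @param tables named list of `feature_table`s, e.g.
#'   `list(mean = ..., T2 = ..., ADC = ...)`.
#' @param cfg an [rf_config()].
#' @param n_train,n_test hold-out sizes passed to [holdout_rf()].
#' @return List with `metrics` (data.frame: modality, task, AUC, accuracy,
#'   NPV, PPV) and `importance` (per modality, a features x tasks matrix of
#'   cross-validated normalized permutation importances).
#' @export
run_modality_comparison <- function(tables, cfg = rf_config(),
                                    n_train = 40L, n_test = 20L) {
  ids <- lapply(tables, function(t) t$patient_id)
  if (length(unique(lapply(ids, identity))) != 1L) {
    stop("feature tables are not aligned on the same patients")
  }
  targets <- sort(unique(tables[[1]]$group))
  rows <- list()
  importance <- list()
  for (mod in names(tables)) {
    imp <- NULL
    for (tg in targets) {
      ho <- holdout_rf(tables[[mod]], tg, n_train, n_test, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        modality = mod, task = ho$task,
        auc = ho$metrics$auc, accuracy = ho$metrics$accuracy,
        npv = ho$metrics$npv, ppv = ho$metrics$ppv,
        stringsAsFactors = FALSE)
      cv <- crossval_rf(tables[[mod]], tg, cfg)
      imp <- cbind(imp, permutation_importance(cv))
    }
    colnames(imp) <- paste0("G", targets, "-vs-rest")
    importance[[mod]] <- imp
  }
  list(metrics = do.call(rbind, rows), importance = importance)
}
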