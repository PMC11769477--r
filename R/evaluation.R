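# Confusion-matrix metrics and the stratified 5-fold cross-validation
# protocol. Per-fold metrics are support-weighted across the two classes
# (so weighted recall equals accuracy, the reporting convention used for
# the summary tables); fold results are averaged arithmetically.

#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred Equal-length binary label vectors.
#' @param positive The label treated as positive (default 1, the herniated
#'   class).
#' @return A `confusion_counts` list with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred, positive = 1L) {
  if (length(y_true) != length(y_pred)) {
    stop_validation("y_true and y_pred lengths differ (%d vs %d)",
                    length(y_true), length(y_pred))
  }
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  structure(list(TP = as.integer(tp), TN = as.integer(tn),
                 FP = as.integer(fp), FN = as.integer(fn)),
            class = "confusion_counts")
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Implements
#' \deqn{Accuracy = (TP + TN) / (TP + TN + FN + FP)}
#' \deqn{Recall = TP / (TP + FN)}
#' \deqn{Precision = TP / (TP + FP)}
#' \deqn{F1 = 2 \cdot Precision \cdot Recall / (Precision + Recall)}
#' A zero denominator in precision or recall yields 0 with a warning.
#'
#' @param counts A [confusion_counts()] with at least one sample.
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(counts) {
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total == 0) stop_validation("no samples to score")
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s denominator is zero; reporting 0", what), call. = FALSE)
      return(0)
    }
    num / den
  }
  precision <- safe_ratio(counts$TP, counts$TP + counts$FP, "precision")
  recall <- safe_ratio(counts$TP, counts$TP + counts$FN, "recall")
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  c(accuracy = (counts$TP + counts$TN) / total,
    precision = precision, recall = recall, f1 = f1)
}

#' Support-weighted metrics over both classes
#'
#' Computes precision, recall and F1 per class (each class in turn as the
#' positive label) and averages them with class-frequency weights. Under
#' this convention weighted recall is algebraically equal to accuracy.
#' Zero-denominator per-class ratios contribute 0 (without warnings, since
#' the complementary class usually dominates the weighted sum).
#'
#' @param y_true,y_pred Equal-length binary label vectors.
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
weighted_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop_validation("y_true and y_pred lengths differ")
  }
  n <- length(y_true)
  if (n == 0) stop_validation("no samples to score")
  classes <- sort(unique(y_true))
  acc <- mean(y_true == y_pred)
  prec <- rec <- f1 <- 0
  for (cl in classes) {
    weight <- mean(y_true == cl)
    cc <- confusion_counts(y_true, y_pred, positive = cl)
    p <- if (cc$TP + cc$FP == 0) 0 else cc$TP / (cc$TP + cc$FP)
    r <- if (cc$TP + cc$FN == 0) 0 else cc$TP / (cc$TP + cc$FN)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    prec <- prec + weight * p
    rec <- rec + weight * r
    f1 <- f1 + weight * f
  }
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

#' Stratified k-fold plan
#'
#' Partitions `1:n` into k folds whose sizes differ by at most one, with
#' per-class stratification: each class is shuffled under the seed and
#' dealt across folds, extras going to the currently smallest folds.
#'
#' @param n Number of samples.
#' @param k Number of folds (default 5).
#' @param seed Shuffle seed.
#' @param labels Class labels used for stratification (default: one
#'   stratum).
#' @return A `fold_plan`: list of k disjoint index vectors covering `1:n`.
#' @export
kfold_split <- function(n, k = 5L, seed = 1L, labels = NULL) {
  if (n < k) stop_validation("n = %d is smaller than k = %d", n, k)
  labels <- labels %||% rep(0L, n)
  if (length(labels) != n) stop_validation("labels must have length n")
  with_seed(seed, {
    folds <- vector("list", k)
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      q <- length(idx) %/% k
      r <- length(idx) %% k
      sizes <- vapply(folds, length, integer(1))
      # q to every fold, the r extras to the currently smallest folds
      extra_folds <- order(sizes, sample.int(k))[seq_len(r)]
      counts <- rep(q, k)
      counts[extra_folds] <- counts[extra_folds] + 1L
      pos <- 1L
      for (f in seq_len(k)) {
        if (counts[f] > 0) {
          folds[[f]] <- c(folds[[f]], idx[pos:(pos + counts[f] - 1L)])
          pos <- pos + counts[f]
        }
      }
    }
    folds <- lapply(folds, sort)
    structure(list(k = as.integer(k), folds = folds, n = as.integer(n)),
              class = "fold_plan")
  })
}

#' Cross-validate the optimizer + classifier pipeline
#'
#' For each fold: the grey wolf optimizer is run on the training portion
#' only (no test-set leakage), the learned weight vector is applied to
#' both portions, the classifier is fitted on the weighted training data
#' and scored on the weighted test data with support-weighted metrics.
#' Pass `gwo_cfg = NULL` to evaluate the unweighted classifier. Per-fold
#' seeds are derived as `seed + fold`, so each fold's behaviour depends
#' only on its own training data.
#'
#' @param features Feature matrix.
#' @param labels Integer binary labels.
#' @param clf_spec A [classifier_spec()] for the final classifier.
#' @param gwo_cfg A [gwo_config()] (its `seed` is overridden per fold), or
#'   `NULL` for unweighted classification.
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold plan and the per-fold derived seeds.
#' @param folds Optional precomputed [kfold_split()] plan.
#' @param keep_models Keep fitted per-fold classifiers in the report.
#' @return A `metrics_report`: fold-averaged `accuracy`, `precision`,
#'   `recall`, `f1`; `per_fold` data frame; `confusion` per fold;
#'   `best_positions` and `traces` per fold (when GWO is used);
#'   `predictions`; `models` (optional).
#' @export
cross_validate <- function(features, labels, clf_spec,
                           gwo_cfg = NULL, k = 5L, seed = 1L,
                           folds = NULL, keep_models = FALSE) {
  if (!is.matrix(features)) features <- as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) stop_validation("features and labels misaligned")
  plan <- folds %||% kfold_split(nrow(features), k = k, seed = seed, labels = labels)
  k <- plan$k
  per_fold <- vector("list", k)
  confusion <- vector("list", k)
  best_positions <- vector("list", k)
  traces <- vector("list", k)
  models <- vector("list", k)
  predictions <- rep(NA_integer_, length(labels))
  for (f in seq_len(k)) {
    test_idx <- plan$folds[[f]]
    train_idx <- setdiff(seq_along(labels), test_idx)
    x_train <- features[train_idx, , drop = FALSE]
    y_train <- labels[train_idx]
    x_test <- features[test_idx, , drop = FALSE]
    if (!is.null(gwo_cfg)) {
      fold_cfg <- gwo_cfg
      fold_cfg$seed <- as.integer(seed + f)
      res <- gwo_optimize(x_train, y_train, fold_cfg)
      best_positions[[f]] <- res$best_position
      traces[[f]] <- res$trace
      x_train <- apply_weights(x_train, res$best_position)
      x_test <- apply_weights(x_test, res$best_position)
    }
    clf <- fit_classifier(clf_spec, x_train, y_train)
    pred <- predict(clf, x_test)
    predictions[test_idx] <- pred
    per_fold[[f]] <- weighted_metrics(labels[test_idx], pred)
    confusion[[f]] <- confusion_counts(labels[test_idx], pred, positive = 1L)
    if (keep_models) models[[f]] <- clf
  }
  per_fold_df <- cbind(data.frame(fold = seq_len(k)),
                       as.data.frame(do.call(rbind, per_fold)))
  mean_metrics <- colMeans(per_fold_df[, c("accuracy", "precision", "recall", "f1")])
  structure(
    list(accuracy = mean_metrics[["accuracy"]],
         precision = mean_metrics[["precision"]],
         recall = mean_metrics[["recall"]],
         f1 = mean_metrics[["f1"]],
         mean = mean_metrics, per_fold = per_fold_df,
         confusion = confusion, best_positions = best_positions,
         traces = traces, predictions = predictions,
         models = if (keep_models) models else NULL,
         k = k, seed = seed),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("<metrics_report %d-fold cross-validation>\n", x$k))
  print(round(x$per_fold[-1], digits))
  cat("fold means:\n")
  print(round(x$mean, digits))
  invisible(x)
}

#' Single stratified train/validation/test evaluation
#'
#' Optional alternative to cross-validation: one stratified split, GWO and
#' the classifier fitted on the training portion, metrics reported on the
#' held-out test portion.
#'
#' @param features,labels Data set.
#' @param clf_spec A [classifier_spec()].
#' @param gwo_cfg Optional [gwo_config()].
#' @param test_fraction Held-out fraction (default 0.2).
#' @param seed Split seed.
#' @return Named metric vector plus attributes `confusion` and
#'   `best_position`.
#' @export
holdout_validate <- function(features, labels, clf_spec, gwo_cfg = NULL,
                             test_fraction = 0.2, seed = 1L) {
  labels <- as.integer(labels)
  split <- stratified_holdout(labels, test_fraction, seed = seed)
  x_train <- features[split$train, , drop = FALSE]
  y_train <- labels[split$train]
  x_test <- features[split$validation, , drop = FALSE]
  best <- NULL
  if (!is.null(gwo_cfg)) {
    res <- gwo_optimize(x_train, y_train, gwo_cfg)
    best <- res$best_position
    x_train <- apply_weights(x_train, best)
    x_test <- apply_weights(x_test, best)
  }
  clf <- fit_classifier(clf_spec, x_train, y_train)
  pred <- predict(clf, x_test)
  out <- weighted_metrics(labels[split$validation], pred)
  attr(out, "confusion") <- confusion_counts(labels[split$validation], pred)
  attr(out, "best_position") <- best
  out
}
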