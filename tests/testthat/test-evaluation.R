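test_that("confusion counts enumerate the four outcomes", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unclass(cc), list(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
  perfect <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$FP + perfect$FN, 0L)
  empty <- confusion_counts(integer(0), integer(0))
  expect_equal(empty$TP + empty$TN + empty$FP + empty$FN, 0L)
  expect_error(confusion_counts(1, c(1, 0)), "lengths differ")
})

test_that("metrics follow the four formulas, including degenerate conventions", {
  m <- classification_metrics(structure(list(TP = 50L, TN = 40L, FP = 5L, FN = 5L),
                                        class = "confusion_counts"))
  expect_equal(m[["accuracy"]], 0.9)
  expect_equal(m[["precision"]], 50 / 55)
  expect_equal(m[["recall"]], 50 / 55)
  expect_equal(m[["f1"]], 50 / 55)
  perfect <- classification_metrics(structure(list(TP = 3L, TN = 4L, FP = 0L, FN = 0L),
                                              class = "confusion_counts"))
  expect_true(all(perfect == 1))
  # nothing predicted positive: the precision denominator is zero -> warn + 0
  expect_warning(
    allneg <- classification_metrics(structure(list(TP = 0L, TN = 2L, FP = 0L, FN = 3L),
                                               class = "confusion_counts")),
    "precision denominator is zero"
  )
  expect_equal(unname(allneg[c("precision", "recall", "f1")]), c(0, 0, 0))
  # TP = 0 with FP, FN > 0: ratios are well-defined zeros
  degenerate <- classification_metrics(structure(list(TP = 0L, TN = 0L, FP = 2L, FN = 3L),
                                                 class = "confusion_counts"))
  expect_equal(unname(degenerate[c("precision", "recall", "f1")]), c(0, 0, 0))
  expect_error(classification_metrics(confusion_counts(integer(0), integer(0))),
               "no samples")
})

test_that("the F1 formula agrees with its 2TP/(2TP+FP+FN) form", {
  set.seed(31)
  for (i in 1:200) {
    cc <- structure(as.list(setNames(as.integer(rmultinom(1, 50, rep(0.25, 4))),
                                     c("TP", "TN", "FP", "FN"))),
                    class = "confusion_counts")
    if (cc$TP + cc$FP == 0 || cc$TP + cc$FN == 0) next
    m <- classification_metrics(cc)
    expect_equal(m[["f1"]], 2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN),
                 tolerance = 1e-12)
  }
})

test_that("support-weighted recall equals accuracy and the symmetric case gives 0.5", {
  wm <- weighted_metrics(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unname(wm), rep(0.5, 4))
  perfect <- weighted_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_true(all(perfect == 1))
  for (s in 1:50) {
    p <- random_predictions(40, seed = s)
    wm <- weighted_metrics(p$y_true, p$y_pred)
    expect_equal(wm[["recall"]], wm[["accuracy"]], tolerance = 1e-12)
  }
})

test_that("stratified folds partition the samples evenly within each class", {
  plan <- kfold_split(10, k = 5, seed = 1)
  expect_true(all(lengths(plan$folds) == 2))
  expect_setequal(unlist(plan$folds), 1:10)
  labels <- rep(c(0L, 1L), c(60, 40))
  plan2 <- kfold_split(100, k = 5, seed = 3, labels = labels)
  for (f in plan2$folds) {
    expect_equal(sum(labels[f] == 0), 12)
    expect_equal(sum(labels[f] == 1), 8)
  }
  # uneven class sizes stay within one sample of proportionality
  labels3 <- rep(c(0L, 1L), c(61, 39))
  plan3 <- kfold_split(100, k = 5, seed = 3, labels = labels3)
  expect_true(all(abs(lengths(plan3$folds) - 20) <= 1))
  counts1 <- vapply(plan3$folds, function(f) sum(labels3[f] == 1), integer(1))
  expect_true(max(counts1) - min(counts1) <= 1)
  expect_identical(kfold_split(30, 5, seed = 9)$folds,
                   kfold_split(30, 5, seed = 9)$folds)
  expect_error(kfold_split(3, k = 5), "smaller than k")
})

test_that("cross-validation bookkeeping, determinism and permutation null behave", {
  d <- synthetic_features(120, 16, 4, 10, seed = 2)
  smoke <- cross_validate(d$features, d$labels, classifier_spec("svm"),
                          NULL, k = 2, seed = 1)
  expect_equal(nrow(smoke$per_fold), 2)
  expect_equal(smoke$accuracy, mean(smoke$per_fold$accuracy))
  # separable features classify nearly perfectly
  full <- cross_validate(d$features, d$labels, classifier_spec("svm"),
                         NULL, k = 5, seed = 1)
  expect_gte(full$accuracy, 0.95)
  # permuting the labels destroys the signal down to the majority rate
  set.seed(5)
  permuted <- sample(d$labels)
  null <- cross_validate(d$features, permuted, classifier_spec("svm"),
                         NULL, k = 5, seed = 1)
  majority <- max(mean(permuted), 1 - mean(permuted))
  expect_lt(abs(null$accuracy - majority), 0.15)
})

test_that("fold metrics are invariant to sample order given a matching plan", {
  d <- synthetic_features(100, 8, 4, 8, seed = 4)
  plan <- kfold_split(100, 5, seed = 6, labels = d$labels)
  r1 <- cross_validate(d$features, d$labels, classifier_spec("svm"),
                       NULL, folds = plan, seed = 6)
  set.seed(10)
  perm <- sample(100)
  plan2 <- plan
  plan2$folds <- lapply(plan$folds, function(ix) sort(match(ix, perm)))
  r2 <- cross_validate(d$features[perm, ], d$labels[perm], classifier_spec("svm"),
                       NULL, folds = plan2, seed = 6)
  expect_equal(r1$per_fold, r2$per_fold, tolerance = 1e-10)
})

test_that("holdout evaluation scores only the held-out stratum", {
  d <- synthetic_features(150, 16, 4, 10, seed = 8)
  res <- holdout_validate(d$features, d$labels, classifier_spec("svm"),
                          gwo_cfg = NULL, test_fraction = 0.2, seed = 3)
  expect_gte(res[["accuracy"]], 0.9)
  expect_s3_class(attr(res, "confusion"), "confusion_counts")
})
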