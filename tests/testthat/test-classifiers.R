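test_that("the four activation functions match their defining formulas", {
  expect_equal(activation("relu", c(-3, 5)), c(0, 5))
  expect_equal(activation("identity", 3.7), 3.7)
  expect_equal(activation("tanh", 0), 0)
  expect_equal(activation("logistic", 0), 0.5)
  x <- seq(-4, 4, by = 0.5)
  expect_equal(activation("tanh", x), tanh(x))
  expect_equal(activation("logistic", x), 1 / (1 + exp(-x)))
  expect_true(all(activation("logistic", x) > 0 & activation("logistic", x) < 1))
  expect_true(all(abs(activation("tanh", x)) < 1))
  expect_error(activation("swish", 1), "unknown activation")
})

test_that("kernel values match their formulas and are symmetric", {
  expect_equal(kernel_value(kernel_spec("linear"), c(1, 2), c(3, 4)), 11)
  expect_equal(kernel_value(kernel_spec("poly", gamma = 1, coef0 = 0, degree = 2),
                            c(1, 1), c(1, 1)), 4)
  expect_error(kernel_value(kernel_spec("linear"), 1:2, 1:3), "lengths differ")
  set.seed(12)
  specs <- list(kernel_spec("linear"),
                kernel_spec("rbf", gamma = 0.7),
                kernel_spec("sigmoid", gamma = 0.3, coef0 = 0.5),
                kernel_spec("poly", gamma = 0.4, coef0 = 1, degree = 3))
  for (i in 1:20) {
    x1 <- rnorm(5); x2 <- rnorm(5)
    for (sp in specs) {
      expect_equal(kernel_value(sp, x1, x2), kernel_value(sp, x2, x1))
    }
    # rbf is 1 at zero distance and bounded in (0, 1]
    expect_equal(kernel_value(specs[[2]], x1, x1), 1)
    r <- kernel_value(specs[[2]], x1, x2)
    expect_true(r > 0 && r <= 1)
    # linear kernel is the degree-1 polynomial with gamma 1, r 0
    expect_equal(kernel_value(kernel_spec("linear"), x1, x2),
                 kernel_value(kernel_spec("poly", gamma = 1, coef0 = 0, degree = 1),
                              x1, x2))
  }
})

test_that("package kernels agree with libsvm's built-in kernels on small instances", {
  data <- make_clusters(n = 60, d = 2, sep = 6, seed = 2)
  set.seed(3)
  probe <- cbind(rnorm(40) * 3 + 3, rnorm(40))
  for (kn in c("linear", "rbf", "poly")) {
    ks <- kernel_spec(kn, gamma = 0.5, coef0 = 1, degree = 2)
    custom <- function(a, b) kernel_value(ks, a, b)
    class(custom) <- "kernel"
    oracle <- kernlab::ksvm(data$x, factor(data$y), kernel = custom, C = 1,
                            scaled = FALSE)
    ours <- fit_classifier(classifier_spec("svm", kernel = ks), data$x, data$y)
    expect_equal(
      as.integer(as.character(kernlab::predict(oracle, probe))),
      predict(ours, probe),
      info = kn
    )
  }
})

test_that("SVM and MLP separate well-separated Gaussian clusters", {
  data <- make_clusters(n = 200, d = 2, sep = 10, seed = 1)
  svm <- fit_classifier(classifier_spec("svm"), data$x, data$y)
  expect_gte(mean(predict(svm, data$x) == data$y), 0.99)
  mlp <- fit_classifier(classifier_spec("mlp", activation = "relu", seed = 1),
                        data$x, data$y)
  expect_gte(mean(predict(mlp, data$x) == data$y), 0.95)
  # every activation can fit the same easy geometry
  for (act in c("identity", "tanh", "logistic")) {
    clf <- fit_classifier(classifier_spec("mlp", activation = act, seed = 1),
                          data$x, data$y)
    expect_gte(mean(predict(clf, data$x) == data$y), 0.9)
  }
})

test_that("degenerate classifier inputs are rejected or handled", {
  data <- make_clusters(n = 40, seed = 5)
  expect_error(fit_classifier(classifier_spec("svm"), data$x, rep(1L, 40)),
               "single class")
  clf <- fit_classifier(classifier_spec("svm"), data$x, data$y)
  expect_identical(predict(clf, data$x[0, , drop = FALSE]), integer(0))
  expect_error(predict(clf, matrix(0, 2, 5)), "5 features")
  dup <- data$x[c(1, 1), ]
  expect_equal(predict(clf, dup)[1], predict(clf, dup)[2])
})

test_that("classifier fits are deterministic given a seed", {
  data <- make_clusters(n = 80, d = 4, sep = 3, seed = 9)
  m1 <- fit_classifier(classifier_spec("mlp", seed = 7), data$x, data$y)
  m2 <- fit_classifier(classifier_spec("mlp", seed = 7), data$x, data$y)
  expect_identical(m1$fit$params, m2$fit$params)
  s1 <- fit_classifier(classifier_spec("svm"), data$x, data$y)
  s2 <- fit_classifier(classifier_spec("svm"), data$x, data$y)
  expect_identical(s1$fit$coefs, s2$fit$coefs)
})
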