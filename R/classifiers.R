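# Final-stage classifiers: SVM (libsvm via e1071) with the four kernel
# families, and an MLP trained by back-propagation with the four
# activations. Feature columns are never rescaled internally — the grey
# wolf weights applied upstream must survive into the decision function.

#' SVM kernel specification
#'
#' The four kernel families:
#' linear \eqn{K(x_1, x_2) = x_1^T x_2};
#' rbf \eqn{K(x_1, x_2) = \exp(-\gamma \|x_1 - x_2\|^2)};
#' sigmoid \eqn{K(x_1, x_2) = \tanh(\gamma x_1^T x_2 + r)};
#' polynomial \eqn{K(x_1, x_2) = (\gamma x_1^T x_2 + r)^d}.
#'
#' @param name `"linear"`, `"rbf"`, `"sigmoid"` or `"poly"`.
#' @param gamma Kernel coefficient \eqn{\gamma > 0}; `NULL` (default) means
#'   the "scale" convention `1 / (n_features * var(x))`, resolved at fit
#'   time.
#' @param coef0 Bias/shift term \eqn{r} (sigmoid and poly; default 0).
#' @param degree Polynomial degree \eqn{d \ge 1} (poly only; default 3).
#' @return A `kernel_spec` list.
#' @export
kernel_spec <- function(name = c("linear", "rbf", "sigmoid", "poly"),
                        gamma = NULL, coef0 = 0, degree = 3L) {
  name <- match.arg(name)
  if (!is.null(gamma) && gamma <= 0) stop_validation("gamma must be > 0")
  if (degree < 1) stop_validation("degree must be >= 1")
  structure(list(name = name, gamma = gamma, coef0 = coef0,
                 degree = as.integer(degree)),
            class = "kernel_spec")
}

#' Evaluate an SVM kernel on two vectors
#'
#' @param spec A [kernel_spec()]. A `NULL` gamma defaults to 1 here (there
#'   is no training matrix to derive the scale convention from).
#' @param x1,x2 Numeric vectors of equal length.
#' @return Scalar kernel value.
#' @examples
#' kernel_value(kernel_spec("linear"), c(1, 2), c(3, 4)) # 11
#' @export
kernel_value <- function(spec, x1, x2) {
  if (!inherits(spec, "kernel_spec")) stop_validation("spec must be a kernel_spec")
  if (length(x1) != length(x2)) {
    stop_validation("vector lengths differ (%d vs %d)", length(x1), length(x2))
  }
  g <- spec$gamma %||% 1
  switch(spec$name,
    linear = sum(x1 * x2),
    rbf = exp(-g * sum((x1 - x2)^2)),
    sigmoid = tanh(g * sum(x1 * x2) + spec$coef0),
    poly = (g * sum(x1 * x2) + spec$coef0)^spec$degree
  )
}

#' Classifier specification
#'
#' Exactly one of `activation` (MLP) or `kernel` (SVM) is used, depending
#' on `family`.
#'
#' @param family `"svm"` or `"mlp"`.
#' @param kernel A [kernel_spec()] (SVM only).
#' @param activation Hidden-layer activation name (MLP only); one of
#'   `"relu"`, `"identity"`, `"tanh"`, `"logistic"`.
#' @param hidden_layers Integer vector of hidden-layer widths (MLP; default
#'   100).
#' @param regularization SVM cost `C` (default 1) or MLP L2 penalty
#'   (default 1e-4).
#' @param max_iterations MLP training iterations (full-batch Adam steps;
#'   default 500).
#' @param learning_rate MLP Adam step size (default 1e-3).
#' @param seed Seed for MLP weight initialization.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(family = c("svm", "mlp"),
                            kernel = kernel_spec("linear"),
                            activation = "relu",
                            hidden_layers = 100L,
                            regularization = NULL,
                            max_iterations = 500L,
                            learning_rate = 1e-3,
                            seed = 0L) {
  family <- match.arg(tolower(family), c("svm", "mlp"))
  if (family == "mlp" && !activation %in% ACTIVATIONS) {
    stop_validation("unknown activation '%s'", activation)
  }
  if (family == "svm" && !inherits(kernel, "kernel_spec")) {
    stop_validation("kernel must be a kernel_spec")
  }
  regularization <- regularization %||% if (family == "svm") 1 else 1e-4
  structure(
    list(family = family,
         kernel = if (family == "svm") kernel else NULL,
         activation = if (family == "mlp") activation else NULL,
         hidden_layers = as.integer(hidden_layers),
         regularization = regularization,
         max_iterations = as.integer(max_iterations),
         learning_rate = learning_rate,
         seed = as.integer(seed)),
    class = "classifier_spec"
  )
}

# sklearn-style "scale" gamma: 1 / (n_features * overall variance).
scale_gamma <- function(x) {
  v <- mean((x - mean(x))^2)
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(x) * v)
}

e1071_kernel_name <- c(linear = "linear", rbf = "radial",
                       sigmoid = "sigmoid", poly = "polynomial")

#' Fit a classifier on a feature matrix
#'
#' SVMs are fitted with libsvm using the specified kernel and no internal
#' column scaling (so upstream per-feature weights shape the decision
#' boundary). MLPs are trained by back-propagation (full-batch Adam,
#' sigmoid output units, element-wise binary cross-entropy) with the
#' specified hidden activation.
#'
#' @param spec A [classifier_spec()].
#' @param features Numeric matrix, one row per sample.
#' @param labels Integer (0/1) or factor labels; at least two classes.
#' @return A `dw_classifier` usable with [predict()].
#' @export
fit_classifier <- function(spec, features, labels) {
  if (!inherits(spec, "classifier_spec")) stop_validation("spec must be a classifier_spec")
  if (!is.matrix(features)) features <- as.matrix(features)
  if (nrow(features) != length(labels)) stop_validation("features and labels misaligned")
  if (anyNA(features) || any(!is.finite(features))) {
    stop_validation("features must be finite")
  }
  classes <- sort(unique(as.integer(labels)))
  if (length(classes) < 2) {
    stop_validation("training labels contain a single class (%s); need at least two",
                    paste(classes, collapse = ","))
  }
  y <- as.integer(labels)
  if (spec$family == "svm") {
    k <- spec$kernel
    fit <- e1071::svm(
      x = features, y = factor(y, levels = classes),
      type = "C-classification",
      kernel = e1071_kernel_name[[k$name]],
      gamma = k$gamma %||% scale_gamma(features),
      coef0 = k$coef0, degree = k$degree,
      cost = spec$regularization, scale = FALSE
    )
  } else {
    fit <- mlp_train(
      features, one_hot(match(y, classes) - 1L, length(classes)),
      hidden_sizes = spec$hidden_layers,
      hidden_activation = spec$activation,
      learning_rate = spec$learning_rate,
      epochs = spec$max_iterations, batch_size = nrow(features),
      l2 = spec$regularization, seed = spec$seed
    )
  }
  structure(
    list(spec = spec, fit = fit, classes = classes,
         n_features = ncol(features), n_samples = nrow(features)),
    class = "dw_classifier"
  )
}

#' Predict class labels
#'
#' @param object A fitted `dw_classifier`.
#' @param newdata Numeric feature matrix with the training feature width.
#' @param ... Unused.
#' @return Integer label vector drawn from the training class set.
#' @export
predict.dw_classifier <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0) return(integer(0))
  if (ncol(newdata) != object$n_features) {
    stop_validation("newdata has %d features but the model was trained on %d",
                    ncol(newdata), object$n_features)
  }
  if (object$spec$family == "svm") {
    as.integer(as.character(stats::predict(object$fit, newdata)))
  } else {
    fwd <- mlp_forward(object$fit$params, newdata, object$fit$hidden_activation)
    object$classes[max.col(fwd$output, ties.method = "first")]
  }
}

#' @export
print.dw_classifier <- function(x, ...) {
  detail <- if (x$spec$family == "svm") {
    sprintf("kernel=%s", x$spec$kernel$name)
  } else {
    sprintf("activation=%s hidden=%s", x$spec$activation,
            paste(x$spec$hidden_layers, collapse = ","))
  }
  cat(sprintf("<dw_classifier %s %s, %d features, %d training samples>\n",
              toupper(x$spec$family), detail, x$n_features, x$n_samples))
  invisible(x)
}
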