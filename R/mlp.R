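# Dense feed-forward network engine: seeded He initialization, selectable
# hidden activation, sigmoid output units trained with element-wise binary
# cross-entropy against one-hot targets, Adam updates. Used both for the
# flatten -> FC -> output classification head of the deep model and for the
# standalone MLP classifier.

#' Activation functions
#'
#' The four activations available to the MLP stage:
#' `relu` \eqn{f(x) = \max(0, x)}, `identity` \eqn{f(x) = x},
#' `tanh` \eqn{f(x) = \tanh(x)}, and `logistic`
#' \eqn{f(x) = 1 / (1 + e^{-x})}. Vectorized element-wise.
#'
#' @param name One of `"relu"`, `"identity"`, `"tanh"`, `"logistic"`.
#' @param x Numeric vector, matrix or array.
#' @return Transformed values, same shape as `x`.
#' @examples
#' activation("relu", c(-3, 5))     # 0 5
#' activation("logistic", 0)        # 0.5
#' @export
activation <- function(name, x) {
  switch(name,
    relu = pmax(x, 0),
    identity = x,
    tanh = tanh(x),
    logistic = 1 / (1 + exp(-x)),
    stop_validation("unknown activation '%s' (use relu, identity, tanh or logistic)", name)
  )
}

# derivative of the activation expressed through pre-activation z and output a
activation_grad <- function(name, z, a) {
  switch(name,
    relu = (z > 0) * 1,
    identity = array(1, dim = dim(z) %||% length(z)),
    tanh = 1 - a^2,
    logistic = a * (1 - a)
  )
}

ACTIVATIONS <- c("relu", "identity", "tanh", "logistic")

mlp_init <- function(layer_sizes, seed = NULL) {
  with_seed(seed, {
    n_layers <- length(layer_sizes) - 1L
    W <- vector("list", n_layers)
    b <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      fan_in <- layer_sizes[l]
      W[[l]] <- matrix(stats::rnorm(fan_in * layer_sizes[l + 1]) * sqrt(2 / fan_in),
                       nrow = fan_in, ncol = layer_sizes[l + 1])
      b[[l]] <- numeric(layer_sizes[l + 1])
    }
    list(W = W, b = b, sizes = layer_sizes)
  })
}

# Forward pass. Hidden layers use `hidden_activation`; the output layer is
# sigmoid (per-unit, matching binary cross-entropy over one-hot targets).
mlp_forward <- function(params, X, hidden_activation) {
  L <- length(params$W)
  zs <- vector("list", L)
  as <- vector("list", L)
  a <- X
  for (l in seq_len(L)) {
    z <- a %*% params$W[[l]] + matrix(params$b[[l]], nrow(a), length(params$b[[l]]), byrow = TRUE)
    zs[[l]] <- z
    a <- if (l < L) activation(hidden_activation, z) else 1 / (1 + exp(-z))
    as[[l]] <- a
  }
  list(z = zs, a = as, output = a, input = X)
}

bce_loss <- function(p, y, eps = 1e-12) {
  p <- clamp(p, eps, 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# One Adam step over the full parameter list; state carries first/second
# moments and the step counter.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (l in seq_along(params$W)) {
    for (nm in c("W", "b")) {
      g <- grads[[nm]][[l]]
      state$m[[nm]][[l]] <- beta1 * state$m[[nm]][[l]] + (1 - beta1) * g
      state$v[[nm]][[l]] <- beta2 * state$v[[nm]][[l]] + (1 - beta2) * g^2
      m_hat <- state$m[[nm]][[l]] / (1 - beta1^state$t)
      v_hat <- state$v[[nm]][[l]] / (1 - beta2^state$t)
      params[[nm]][[l]] <- params[[nm]][[l]] - lr * m_hat / (sqrt(v_hat) + eps)
    }
  }
  list(params = params, state = state)
}

adam_state <- function(params) {
  zeros <- function(p) lapply(p, function(x) x * 0)
  list(m = list(W = zeros(params$W), b = zeros(params$b)),
       v = list(W = zeros(params$W), b = zeros(params$b)),
       t = 0L)
}

mlp_gradients <- function(params, fwd, Y, hidden_activation, l2 = 0) {
  L <- length(params$W)
  n <- nrow(Y)
  gW <- vector("list", L)
  gb <- vector("list", L)
  # sigmoid + BCE: dL/dz at the output simplifies to (a - y) / n
  delta <- (fwd$a[[L]] - Y) / n
  for (l in seq(L, 1)) {
    a_prev <- if (l == 1) fwd$input else fwd$a[[l - 1]]
    gW[[l]] <- crossprod(a_prev, delta) + l2 * params$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(params$W[[l]])) *
        activation_grad(hidden_activation, fwd$z[[l - 1]], fwd$a[[l - 1]])
    }
  }
  list(W = gW, b = gb)
}

# Train a dense network with Adam on mini-batches. `Y` is one-hot. Returns
# the fitted parameters plus a per-epoch loss/accuracy trace.
mlp_train <- function(X, Y, hidden_sizes, hidden_activation = "relu",
                      learning_rate = 1e-4, epochs = 50L,
                      batch_size = nrow(X), l2 = 0, seed = NULL,
                      init = NULL) {
  if (!hidden_activation %in% ACTIVATIONS) {
    stop_validation("unknown activation '%s'", hidden_activation)
  }
  sizes <- c(ncol(X), hidden_sizes, ncol(Y))
  with_seed(seed, {
    params <- init %||% mlp_init(sizes, seed = NULL)
    state <- adam_state(params)
    trace <- data.frame(epoch = integer(0), loss = numeric(0), accuracy = numeric(0))
    n <- nrow(X)
    batch_size <- min(batch_size, n)
    for (ep in seq_len(epochs)) {
      order_idx <- if (batch_size < n) sample.int(n) else seq_len(n)
      starts <- seq(1, n, by = batch_size)
      for (s in starts) {
        idx <- order_idx[s:min(s + batch_size - 1, n)]
        fwd <- mlp_forward(params, X[idx, , drop = FALSE], hidden_activation)
        grads <- mlp_gradients(params, fwd, Y[idx, , drop = FALSE],
                               hidden_activation, l2 = l2)
        if (learning_rate > 0) {
          upd <- adam_step(params, grads, state, lr = learning_rate)
          params <- upd$params
          state <- upd$state
        }
      }
      full <- mlp_forward(params, X, hidden_activation)
      pred <- max.col(full$output, ties.method = "first")
      truth <- max.col(Y, ties.method = "first")
      trace <- rbind(trace, data.frame(
        epoch = ep, loss = bce_loss(full$output, Y),
        accuracy = mean(pred == truth)
      ))
    }
    list(params = params, trace = trace, hidden_activation = hidden_activation)
  })
}
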