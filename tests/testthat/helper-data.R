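# Shared fixtures, built in code.

# Two Gaussian clusters in d dimensions whose means are `sep` standard
# deviations apart along the first axis.
make_clusters <- function(n = 200, d = 2, sep = 10, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    y <- rep(0:1, length.out = n)
    x <- matrix(rnorm(n * d), n, d)
    x[, 1] <- x[, 1] + y * sep
    list(x = x, y = y)
  })
}

# Random binary truth/prediction pair of length n.
random_predictions <- function(n, seed) {
  set.seed(seed)
  list(y_true = rbinom(n, 1, runif(1, 0.2, 0.8)),
       y_pred = rbinom(n, 1, runif(1, 0.2, 0.8)))
}
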