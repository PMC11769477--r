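# Internal helpers shared across modules.

stop_validation <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the R random seed, evaluates `code`, and restores the caller's RNG
#' state afterwards so seeded package functions never perturb the user's
#' random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Stratified holdout split: per-class seeded shuffle, `fraction` of each
# class held out for validation. Guarantees both partitions see every class.
stratified_holdout <- function(labels, fraction = 0.2, seed = NULL) {
  if (fraction <= 0 || fraction >= 1) {
    stop_validation("validation fraction must be in (0, 1), got %s", fraction)
  }
  with_seed(seed, {
    classes <- sort(unique(labels))
    val <- integer(0)
    for (cl in classes) {
      idx <- which(labels == cl)
      if (length(idx) < 2) {
        stop_validation(
          "class '%s' has %d sample(s); stratified splitting needs at least 2 per class",
          cl, length(idx)
        )
      }
      n_val <- max(1L, min(length(idx) - 1L, round(fraction * length(idx))))
      val <- c(val, sample(idx, n_val))
    }
    val <- sort(val)
    list(train = setdiff(seq_along(labels), val), validation = val)
  })
}
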