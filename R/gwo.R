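# Grey wolf optimization of a per-feature weight vector with wrapper
# (classifier-accuracy) fitness. Each wolf is a candidate weight vector;
# its fitness is the validation accuracy of a classifier trained on the
# column-weighted feature matrix. The three fittest wolves (alpha, beta,
# delta) lead: every wolf moves to the leader mean plus a uniform
# perturbation whose amplitude `a` decays linearly to zero, shrinking the
# search around the leaders as iterations progress:
#
#   positions = (alpha + beta + delta) / 3 + a * (rand() - 0.5)
#
# The perturbation is drawn independently per wolf and per dimension so
# the pack explores a cloud around the leader mean rather than collapsing
# to a single point. The original encircling update (A, C, D vectors) is
# available as update_rule = "canonical" for comparison.

#' Grey wolf optimizer configuration
#'
#' @param dimension Number of feature columns being weighted.
#' @param population_size Number of wolves (>= 3 so alpha, beta and delta
#'   exist; default 30).
#' @param iterations Number of iterations (default 50).
#' @param bounds Numeric `c(lo, hi)` box for every coordinate (default
#'   `c(0, 1)`: multiplicative weights between drop and keep).
#' @param a_initial Starting value of the linearly decaying perturbation
#'   coefficient (default 2).
#' @param seed Seed making the whole run reproducible.
#' @param fitness_spec [classifier_spec()] used inside the fitness
#'   function (default: linear-kernel SVM, the headline configuration).
#' @param validation_fraction Fraction of samples held out (stratified)
#'   for fitness scoring; fixed once per run so all wolves are scored on
#'   the same split (default 0.2).
#' @param update_rule `"simplified"` (leader mean + decaying uniform
#'   noise, the default) or `"canonical"` (the original encircling
#'   equations).
#' @return A `gwo_config` list.
#' @export
gwo_config <- function(dimension, population_size = 30L, iterations = 50L,
                       bounds = c(0, 1), a_initial = 2, seed = 1L,
                       fitness_spec = classifier_spec("svm"),
                       validation_fraction = 0.2,
                       update_rule = c("simplified", "canonical")) {
  update_rule <- match.arg(update_rule)
  if (population_size < 3) {
    stop_validation("population_size must be >= 3 so alpha, beta and delta exist")
  }
  if (iterations < 1) stop_validation("iterations must be >= 1")
  if (length(bounds) != 2 || bounds[1] >= bounds[2]) {
    stop_validation("bounds must be c(lo, hi) with lo < hi")
  }
  if (dimension < 1) stop_validation("dimension must be >= 1")
  structure(
    list(dimension = as.integer(dimension),
         population_size = as.integer(population_size),
         iterations = as.integer(iterations),
         bounds = as.numeric(bounds), a_initial = a_initial,
         seed = as.integer(seed), fitness_spec = fitness_spec,
         validation_fraction = validation_fraction,
         update_rule = update_rule),
    class = "gwo_config"
  )
}

#' Wrapper fitness: validation accuracy of weighted-feature classification
#'
#' For each candidate position, scales the feature columns by the
#' position, fits `fitness_spec` on the training split and returns the
#' accuracy on the validation split. Deterministic given the split and the
#' classifier seed.
#'
#' @param positions Matrix (wolves x dimension) of candidate weight
#'   vectors.
#' @param features Feature matrix (samples x dimension).
#' @param labels Integer class labels.
#' @param fitness_spec A [classifier_spec()].
#' @param split List with `train` and `validation` index vectors, e.g.
#'   from the stratified holdout used inside [gwo_optimize()].
#' @return Numeric fitness (accuracy) vector, one entry per wolf.
#' @export
evaluate_fitness <- function(positions, features, labels, fitness_spec, split) {
  if (ncol(positions) != ncol(features)) {
    stop_validation("position dimension %d does not match feature count %d",
                    ncol(positions), ncol(features))
  }
  y_train <- labels[split$train]
  y_val <- labels[split$validation]
  if (length(unique(y_train)) < 2) {
    stop_validation("a class is absent from the training split; use a stratified split")
  }
  apply(positions, 1, function(w) {
    weighted <- sweep(features, 2, w, "*")
    clf <- fit_classifier(fitness_spec, weighted[split$train, , drop = FALSE], y_train)
    pred <- predict(clf, weighted[split$validation, , drop = FALSE])
    mean(pred == y_val)
  })
}

#' Initialize the wolf pack
#'
#' Draws positions uniformly inside the bounds under the configured seed,
#' evaluates fitness once, and ranks the leaders.
#'
#' @param cfg A [gwo_config()].
#' @param features,labels Data for the wrapper fitness.
#' @param split Optional pre-computed train/validation split (defaults to
#'   a stratified holdout drawn under `cfg$seed`).
#' @return A `pack_state` list: `positions`, `fitness`, `alpha`, `beta`,
#'   `delta` (each `list(position, fitness, index)`), `global_best`,
#'   `iteration`, `a_current`, `split`.
#' @export
initialize_pack <- function(cfg, features, labels, split = NULL) {
  with_seed(cfg$seed, init_pack_(cfg, features, labels, split))
}

# Unseeded worker: draws from the current RNG stream so gwo_optimize() can
# run initialization and the iteration loop under a single seed.
init_pack_ <- function(cfg, features, labels, split = NULL) {
  if (ncol(features) != cfg$dimension) {
    stop_validation("cfg$dimension is %d but features have %d columns",
                    cfg$dimension, ncol(features))
  }
  split <- split %||% stratified_holdout(labels, cfg$validation_fraction,
                                         seed = NULL)
  positions <- matrix(stats::runif(cfg$population_size * cfg$dimension,
                                   cfg$bounds[1], cfg$bounds[2]),
                      nrow = cfg$population_size, ncol = cfg$dimension)
  fitness <- evaluate_fitness(positions, features, labels, cfg$fitness_spec, split)
  state <- structure(
    list(positions = positions, fitness = fitness,
         alpha = NULL, beta = NULL, delta = NULL, global_best = NULL,
         iteration = 0L, a_current = cfg$a_initial, split = split),
    class = "pack_state"
  )
  rank_leaders(state)
}

#' Rank the pack leaders
#'
#' Sets alpha, beta and delta to the three fittest wolves (ties broken by
#' lower wolf index) and updates the elitist global best, which never
#' degrades across iterations.
#'
#' @param state A `pack_state`.
#' @return The updated `pack_state`.
#' @export
rank_leaders <- function(state) {
  if (length(state$fitness) < 3) {
    stop_validation("at least 3 wolves are required to rank alpha, beta and delta")
  }
  ord <- order(-state$fitness, seq_along(state$fitness))
  pick <- function(i) list(position = state$positions[ord[i], ],
                           fitness = state$fitness[ord[i]], index = ord[i])
  state$alpha <- pick(1)
  state$beta <- pick(2)
  state$delta <- pick(3)
  if (is.null(state$global_best) ||
      state$alpha$fitness > state$global_best$fitness) {
    state$global_best <- state$alpha[c("position", "fitness")]
  }
  state
}

#' Linearly decaying perturbation coefficient
#'
#' \eqn{a(t) = a_{initial} (1 - t / T)}: starts at `a_initial` at t = 0
#' and reaches 0 at t = T.
#'
#' @param cfg A [gwo_config()].
#' @param iteration Iteration counter `t`, `0 <= t <= iterations`.
#' @return The coefficient value.
#' @export
update_coefficient <- function(cfg, iteration) {
  if (iteration < 0 || iteration > cfg$iterations) {
    stop_validation("iteration %d outside [0, %d]", iteration, cfg$iterations)
  }
  cfg$a_initial * (1 - iteration / cfg$iterations)
}

#' Move every wolf toward the leaders
#'
#' Simplified rule: every wolf lands on the component-wise mean of alpha,
#' beta and delta plus `a_current * (u - 0.5)` with u drawn independently
#' per wolf and per dimension; results are clamped to the bounds. The
#' canonical rule applies the original encircling equations instead.
#' Consumes the current RNG stream (seeded by [gwo_optimize()]).
#'
#' @param state A ranked `pack_state`.
#' @param a_current Perturbation coefficient from [update_coefficient()].
#' @param cfg A [gwo_config()].
#' @return The state with updated `positions` (fitness not yet
#'   re-evaluated).
#' @export
update_positions <- function(state, a_current, cfg) {
  n <- nrow(state$positions)
  d <- ncol(state$positions)
  if (cfg$update_rule == "simplified") {
    base <- (state$alpha$position + state$beta$position + state$delta$position) / 3
    noise <- matrix(stats::runif(n * d) - 0.5, n, d) * a_current
    new_pos <- matrix(base, n, d, byrow = TRUE) + noise
  } else {
    new_pos <- state$positions
    leaders <- list(state$alpha$position, state$beta$position, state$delta$position)
    for (i in seq_len(n)) {
      contrib <- vapply(leaders, function(lead) {
        A <- 2 * a_current * stats::runif(d) - a_current
        C <- 2 * stats::runif(d)
        D <- abs(C * lead - state$positions[i, ])
        lead - A * D
      }, numeric(d))
      new_pos[i, ] <- rowMeans(contrib)
    }
  }
  state$positions <- clamp(new_pos, cfg$bounds[1], cfg$bounds[2])
  state
}

#' Optimize per-feature weights by grey wolf search
#'
#' Runs the full loop: seeded uniform initialization, wrapper-fitness
#' evaluation, leader ranking, and position updates with the linearly
#' decaying coefficient. The convergence trace records the elitist global
#' best per iteration and is therefore monotone non-decreasing; with
#' `iterations = 1` only the initial pack is evaluated.
#'
#' @param features Feature matrix (samples x dimension).
#' @param labels Integer class labels aligned with `features`.
#' @param cfg A [gwo_config()]; `cfg$dimension` must equal
#'   `ncol(features)`.
#' @return A `gwo_result`: `best_position` (the learned weight vector),
#'   `best_fitness`, `trace` (length `iterations`), and `config`.
#' @export
gwo_optimize <- function(features, labels, cfg) {
  if (!inherits(cfg, "gwo_config")) stop_validation("cfg must be a gwo_config")
  if (nrow(features) != length(labels)) stop_validation("features and labels misaligned")
  with_seed(cfg$seed, {
    state <- init_pack_(cfg, features, labels)
    trace <- numeric(cfg$iterations)
    trace[1] <- state$global_best$fitness
    t <- 1L
    while (t < cfg$iterations) {
      a <- update_coefficient(cfg, t)
      state <- update_positions(state, a, cfg)
      state$fitness <- evaluate_fitness(state$positions, features, labels,
                                        cfg$fitness_spec, state$split)
      state <- rank_leaders(state)
      state$iteration <- t
      state$a_current <- a
      t <- t + 1L
      trace[t] <- state$global_best$fitness
    }
    structure(
      list(best_position = state$global_best$position,
           best_fitness = state$global_best$fitness,
           trace = trace, config = cfg),
      class = "gwo_result"
    )
  })
}

#' @export
print.gwo_result <- function(x, ...) {
  cat(sprintf(
    "<gwo_result %d-dim, %d wolves x %d iterations, best fitness %.4f>\n",
    x$config$dimension, x$config$population_size, x$config$iterations,
    x$best_fitness
  ))
  invisible(x)
}

#' Apply a learned weight vector to a feature matrix
#'
#' Element-wise column scaling: `out[i, j] = features[i, j] * weights[j]`.
#'
#' @param features Feature matrix.
#' @param weights Weight vector of length `ncol(features)` (or a
#'   `gwo_result`, whose `best_position` is used).
#' @return The weighted feature matrix.
#' @export
apply_weights <- function(features, weights) {
  if (inherits(weights, "gwo_result")) weights <- weights$best_position
  if (length(weights) != ncol(features)) {
    stop_validation("weight length %d does not match feature count %d",
                    length(weights), ncol(features))
  }
  sweep(features, 2, weights, "*")
}
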