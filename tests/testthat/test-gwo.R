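# A small wrapper-fitness problem reused across the optimizer tests.
gwo_problem <- function(n = 120, d = 16, sep = 3, seed = 5) {
  synthetic_features(n_samples = n, n_features = d, n_informative = 4,
                     class_separation = sep, seed = seed)
}

test_that("pack initialization is seeded, bounded and correctly shaped", {
  d <- gwo_problem()
  cfg <- gwo_config(16, population_size = 5, iterations = 3, seed = 42)
  s1 <- initialize_pack(cfg, d$features, d$labels)
  s2 <- initialize_pack(cfg, d$features, d$labels)
  expect_identical(s1$positions, s2$positions)
  expect_equal(dim(s1$positions), c(5, 16))
  expect_length(s1$fitness, 5)
  expect_true(all(s1$positions >= 0 & s1$positions <= 1))
  expect_error(initialize_pack(gwo_config(8), d$features, d$labels), "dimension")
  expect_error(gwo_config(16, population_size = 2), "alpha, beta and delta")
})

test_that("leader ranking orders by fitness with index tie-breaks and is elitist", {
  st <- structure(list(positions = matrix(1:8, 4, 2), fitness = c(0.2, 0.9, 0.5, 0.9),
                       global_best = NULL), class = "pack_state")
  st <- rank_leaders(st)
  expect_equal(st$alpha$index, 2)
  expect_equal(st$beta$index, 4) # tied with alpha, higher index
  expect_equal(st$delta$index, 3)
  # pure tie-break: all equal -> first three wolves
  st2 <- structure(list(positions = matrix(0, 4, 2), fitness = rep(0.5, 4),
                        global_best = NULL), class = "pack_state")
  st2 <- rank_leaders(st2)
  expect_equal(c(st2$alpha$index, st2$beta$index, st2$delta$index), 1:3)
  # elitism: a worse generation never degrades the global best
  st$fitness <- c(0.1, 0.7, 0.2, 0.3)
  st <- rank_leaders(st)
  expect_equal(st$global_best$fitness, 0.9)
})

test_that("the reduction coefficient decays linearly from a_initial to zero", {
  cfg <- gwo_config(4, iterations = 10, a_initial = 2)
  expect_equal(update_coefficient(cfg, 0), 2)
  expect_equal(update_coefficient(cfg, 5), 1)
  expect_equal(update_coefficient(cfg, 10), 0)
  expect_error(update_coefficient(cfg, 11), "outside")
})

test_that("position updates collapse to the leader mean when a = 0 and stay within a/2 otherwise", {
  cfg <- gwo_config(2, population_size = 5, iterations = 2, bounds = c(-10, 10))
  st <- structure(list(positions = matrix(rnorm(10), 5, 2),
                       fitness = c(5, 4, 3, 2, 1), global_best = NULL),
                  class = "pack_state")
  st <- rank_leaders(st)
  st$alpha$position <- c(0, 0); st$beta$position <- c(1, 1); st$delta$position <- c(2, 2)
  collapsed <- update_positions(st, a_current = 0, cfg)
  expect_true(all(apply(collapsed$positions, 1, function(p) all(p == c(1, 1)))))
  set.seed(1)
  moved <- update_positions(st, a_current = 0.8, cfg)
  expect_true(all(abs(moved$positions - 1) <= 0.4 + 1e-12))
})

test_that("whole optimization runs are bit-reproducible and iteration 1 returns the best initial wolf", {
  d <- gwo_problem()
  cfg <- gwo_config(16, population_size = 6, iterations = 4, seed = 77)
  r1 <- gwo_optimize(d$features, d$labels, cfg)
  r2 <- gwo_optimize(d$features, d$labels, cfg)
  expect_identical(r1, r2)
  expect_length(r1$trace, 4)
  expect_false(is.unsorted(r1$trace))
  one <- gwo_optimize(d$features, d$labels,
                      gwo_config(16, population_size = 6, iterations = 1, seed = 77))
  init <- initialize_pack(gwo_config(16, population_size = 6, iterations = 1, seed = 77),
                          d$features, d$labels)
  expect_identical(one$best_position, init$global_best$position)
  expect_identical(one$best_fitness, max(init$fitness))
  # the canonical encircling update also runs and respects bounds
  canon <- gwo_optimize(d$features, d$labels,
                        gwo_config(16, 6, 3, seed = 1, update_rule = "canonical"))
  expect_true(all(canon$best_position >= 0 & canon$best_position <= 1))
})

test_that("wrapper fitness scores separability, annihilation and duplicates correctly", {
  d <- synthetic_features(200, 16, 4, 10, class_balance = 0.65, seed = 3)
  split <- discwolf:::stratified_holdout(d$labels, 0.2, seed = 9)
  spec <- classifier_spec("svm")
  # direct-fit oracle: the construction is separable
  direct <- fit_classifier(spec, d$features, d$labels)
  expect_gte(mean(predict(direct, d$features) == d$labels), 0.995)
  ones <- evaluate_fitness(matrix(1, 1, 16), d$features, d$labels, spec, split)
  expect_equal(ones, 1)
  # all-zero weights annihilate the features -> majority-vote oracle
  zero <- evaluate_fitness(matrix(0, 1, 16), d$features, d$labels, spec, split)
  majority <- as.integer(mean(d$labels[split$train]) > 0.5)
  expect_equal(zero, mean(d$labels[split$validation] == majority))
  dup <- evaluate_fitness(matrix(0.5, 2, 16), d$features, d$labels, spec, split)
  expect_equal(dup[1], dup[2])
})

test_that("feature weighting is element-wise column scaling", {
  f <- matrix(c(3, 5, 7), 1, 3)
  expect_equal(apply_weights(f, c(2, 0, 1)), matrix(c(6, 0, 7), 1, 3))
  expect_equal(apply_weights(f, rep(1, 3)), f)
  expect_true(all(apply_weights(f, rep(0, 3)) == 0))
  expect_error(apply_weights(f, 1:2), "does not match")
})

test_that("weighted classification beats unweighted when the fitness signal is not saturated", {
  # positive-control regime: moderate separation and a half-split fitness
  # validation keep wrapper accuracy below 1, so selection pressure is real
  diffs <- vapply(1:10, function(s) {
    d <- synthetic_features(400, 64, 8, 2, seed = s)
    g <- gwo_config(64, population_size = 15, iterations = 25,
                    validation_fraction = 0.5)
    w <- cross_validate(d$features, d$labels, classifier_spec("svm"), g,
                        k = 5, seed = s)$accuracy
    u <- cross_validate(d$features, d$labels, classifier_spec("svm"), NULL,
                        k = 5, seed = s)$accuracy
    w - u
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})
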