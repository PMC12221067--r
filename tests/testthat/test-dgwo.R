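test_that("swimming-bird update reproduces fixed points and hand cases", {
  expect_equal(dto_swim_update(c(0.3, 0.7), c(0.3, 0.7), 1, 1), c(0.3, 0.7))
  expect_equal(dto_swim_update(0.2, 0.8, 1, 1), 0.2)  # 0.8 - |0.8 - 0.2|
  expect_equal(dto_swim_update(c(0.1, 0.9), c(0.5, 0.4), 0, 2), c(0.5, 0.4))
})

test_that("flying-bird update reproduces fixed points and hand cases", {
  r <- dto_fly_update(0.5, 0, 0.5, 0.5, 0.9, 1.5, 1.5, 0.7)
  expect_equal(r$speed, 0)
  expect_equal(r$position, 0.5)
  r2 <- dto_fly_update(0.2, 0.1, 0.5, 0.8, 0.9, 1.5, 1.5, 0.5)
  expect_equal(r2$speed, 0.09 + 0.225 + 0.45)
  expect_equal(r2$position, min(1, 0.2 + 0.765))
  r3 <- dto_fly_update(0.4, 0.2, 0.9, 0.9, 0, 1.5, 1.5, 0)
  expect_equal(r3$speed, 0)
  expect_equal(r3$position, 0.4)
})

test_that("grey-wolf step collapses onto coincident leaders at l = 0", {
  pos <- matrix(runif(8), 4, 2)
  leaders <- matrix(0.35, 3, 2)
  out <- gwo_step(pos, leaders, l = 0)
  expect_equal(out, matrix(0.35, 4, 2))
  # hand case: r1 = r2 = 0.5, l = 1 -> a = 0, c = 1; all x' = leader
  out2 <- gwo_step(matrix(0.2, 1, 1), matrix(0.6, 3, 1), l = 1,
                   runif_fn = function(n) rep(0.5, n))
  expect_equal(as.vector(out2), 0.6)
  # clipping contract under wide draws
  set.seed(21)
  out3 <- gwo_step(matrix(runif(20), 10, 2),
                   matrix(runif(6), 3, 2), l = 2)
  expect_true(all(out3 >= 0 & out3 <= 1))
  expect_error(gwo_step(pos, leaders[1:2, , drop = FALSE], 1), "3")
})

test_that("binarisation is strict and monotone in the threshold", {
  expect_equal(binarize_position(c(0.2, 0.5, 0.8), 0.5), c(0L, 0L, 1L))
  expect_equal(binarize_position(rep(0.9, 4), 0.5), rep(1L, 4))
  p <- runif(20)
  m1 <- binarize_position(p, 0.3)
  m2 <- binarize_position(p, 0.7)
  expect_true(all(m2 <= m1))
  expect_error(binarize_position(p, 1), "threshold")
})

test_that("classification-error fitness honours its contracts", {
  tbl <- make_feature_dataset(n_per_class = 20, n_informative = 1,
                              n_noise = 2, effect_size = 200, seed = 2)
  inf_col <- attr(tbl, "informative_idx")
  mask <- rep(0L, 3); mask[inf_col] <- 1L
  expect_equal(fitness_classification_error(mask, tbl), 0)
  expect_equal(fitness_classification_error(c(0L, 0L, 0L), tbl), 1)
  expect_gte(fitness_classification_error(rep(1L, 3), tbl), 0)
  un <- feature_table(matrix(rnorm(20), 10, 2))
  expect_error(fitness_classification_error(c(1L, 0L), un), "labels")
  one <- feature_table(matrix(rnorm(20), 10, 2), labels = rep(1, 10))
  expect_error(fitness_classification_error(c(1L, 0L), one), "single-class")
})

test_that("selector stays within 0.02 of the exhaustive optimum (8+/10)", {
  hits <- 0
  for (seed in 1:10) {
    tb <- make_feature_dataset(n_per_class = 25, n_informative = 2,
                               n_noise = 8, effect_size = 4, seed = seed)
    ex <- exhaustive_best_mask(tb, fold_seed = seed + 104729L)
    sel <- dgwo_select(tb, list(n_agents = 10, max_iter = 30, seed = seed))
    if (sel$best_fitness - ex$fitness <= 0.02) hits <- hits + 1
    expect_true(all(diff(sel$fitness_trace) <= 0))
    expect_gte(ex$fitness, 0)
    expect_lte(ex$fitness, sel$best_fitness)  # oracle optimality bound
  }
  expect_gte(hits, 8)
})

test_that("selector output is deterministic and beats the all-features mask", {
  tb <- make_feature_dataset(n_per_class = 30, n_informative = 2,
                             n_noise = 8, effect_size = 4, seed = 1)
  s1 <- dgwo_select(tb, list(n_agents = 10, max_iter = 30, seed = 1))
  s2 <- dgwo_select(tb, list(n_agents = 10, max_iter = 30, seed = 1))
  expect_identical(s1[c("mask", "best_fitness", "fitness_trace")],
                   s2[c("mask", "best_fitness", "fitness_trace")])
  all_fit <- fitness_classification_error(rep(1L, 10), tb,
                                          fold_seed = 1 + 104729L)
  expect_lte(s1$best_fitness, all_fit)
  expect_identical(binarize_position(s1$best_position,
                                     s1$config$binarize_threshold), s1$mask)
  expect_error(dgwo_select(tb, list(n_agents = 3)), "4 agents")
})

test_that("exhaustive oracle resolves ties to fewer features", {
  # one informative feature duplicated: singleton masks tie; the rule picks
  # a single-feature mask, never the pair
  set.seed(4)
  y <- rep(c(0, 1), each = 15)
  x <- rnorm(30) + 3 * y
  tb <- feature_table(cbind(x, x, rnorm(30)),
                      feature_names = c("a", "b", "c"), labels = y)
  ex <- exhaustive_best_mask(tb)
  expect_equal(sum(ex$mask), 1)
  expect_error(exhaustive_best_mask(
    feature_table(matrix(rnorm(40 * 17), 40, 17),
                  labels = rep(c(0, 1), 20))), "refusing")
})
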