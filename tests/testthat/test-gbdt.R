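test_that("constant residuals give a single-leaf tree", {
  tr <- fit_tree(matrix(1:6), rep(4.2, 6), max_depth = 3)
  expect_equal(nrow(tr$nodes), 1L)
  expect_equal(predict(tr, matrix(c(-10, 0, 10))), rep(4.2, 3))
})

test_that("two separable points split exactly between them", {
  tr <- fit_tree(matrix(c(0, 1)), c(0, 10), max_depth = 1)
  expect_false(tr$nodes$is_leaf[1])
  expect_equal(tr$nodes$threshold[1], 0.5)
  expect_equal(predict(tr, matrix(c(0.4, 0.6))), c(0, 10))
})

test_that("a depth-2 tree solves the XOR layout exactly", {
  x <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c(0, 10, 10, 0)
  tr <- fit_tree(x, y, max_depth = 2)
  expect_equal(predict(tr, x), y)
})

test_that("greedy stumps match exhaustive search on small samples", {
  set.seed(77)
  for (rep in 1:12) {
    n <- sample(4:12, 1)
    x <- matrix(round(rnorm(n * 2), 2), n, 2)
    y <- rnorm(n)
    tr <- fit_tree(x, y, max_depth = 1)
    sse <- sum((y - predict(tr, x))^2)
    expect_equal(sse, brute_force_stump_sse(x, y), tolerance = 1e-10)
  }
})

test_that("deterministic tie-breaking prefers low feature index and threshold", {
  # duplicated feature columns: both split perfectly, column 1 must win
  x <- cbind(a = c(0, 0, 1, 1), b = c(0, 0, 1, 1))
  tr <- fit_tree(x, c(1, 1, 5, 5), max_depth = 1)
  expect_equal(tr$nodes$feature[1], 1L)
})

test_that("a single tree with full shrinkage is the boosting base case", {
  set.seed(5)
  x <- matrix(rnorm(60), 30, 2)
  y <- x[, 1] - 2 * x[, 2] + rnorm(30, sd = 0.1)
  single <- fit_tree(x, y, max_depth = 3)
  boost <- gbdt_fit(x, y, n_trees = 1, shrinkage = 1, max_depth = 3)
  expect_equal(predict(boost, x), predict(single, x))
})

test_that("a constant target is fit exactly in one round", {
  x <- matrix(rnorm(20), 10, 2)
  fit <- gbdt_fit(x, rep(7, 10), n_trees = 1, shrinkage = 1)
  expect_equal(fitted(fit), rep(7, 10))
})

test_that("staged training error is monotone and a step function is learned", {
  x <- matrix(seq(0, 1, length.out = 50))
  y <- ifelse(x[, 1] > 0.5, 10, 0)
  fit <- gbdt_fit(x, y, n_trees = 200, shrinkage = 0.1, max_depth = 1)
  expect_true(all(diff(fit$train_mse) <= 1e-12))
  expect_lt(fit$train_mse[200], 1e-3)
})

test_that("with unlimited depth and full shrinkage one tree interpolates", {
  set.seed(8)
  x <- matrix(rnorm(25), 25, 1)
  y <- rnorm(25)
  fit <- gbdt_fit(x, y, n_trees = 1, shrinkage = 1, max_depth = 30)
  expect_lt(fit$train_mse[1], 1e-20)
})

test_that("staged prediction at full length equals predict", {
  set.seed(9)
  x <- matrix(rnorm(40), 20, 2)
  y <- rowSums(x)
  fit <- gbdt_fit(x, y, n_trees = 25, shrinkage = 0.2)
  expect_equal(predict(fit, x, n_trees = 25), predict(fit, x))
  expect_equal(predict(fit, x, n_trees = 0), rep(0, 20)) # f0 = 0
  expect_error(predict(fit, x[, 1, drop = FALSE]), "feature")
  expect_error(predict(fit, x, n_trees = 26), "only")
})

test_that("boosting beats the constant predictor on a noisy monotone signal", {
  m <- generate_cohort(cohort_spec(1, seed = 4, noise_sd = 3))[[1]]
  tt <- seq(0, 50, length.out = 500)
  fs <- generate_eeg_features(m, tt, seed = 12, n_informative = 2,
                              n_distractors = 2)
  idx <- seq(1, 500, by = 2)
  fit <- gbdt_fit(fs$features[idx, ], fs$target[idx], n_trees = 100,
                  max_depth = 3, min_samples_leaf = 10)
  r2_test <- r_squared(fs$target[-idx],
                       predict(fit, fs$features[-idx, ]))
  expect_gte(r2_test, 0.5) # constant predictor scores 0
})
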