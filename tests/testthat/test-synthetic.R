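test_that("cohort generation is seeded and respects the ranges", {
  spec <- cohort_spec(10, seed = 21)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_equal(a, b)
  expect_length(a, 10L)
  ages <- sapply(a, function(m) m$patient$age)
  expect_true(all(ages >= 65 & ages <= 85))
  for (m in a) {
    tru <- unlist(m$pd_true)
    expect_true(tru["e0"] >= 85 && tru["e0"] <= 95)
    expect_true(tru["ec50"] >= 1.5 && tru["ec50"] <= 4)
    # truth inside the default identification bounds
    expect_true(all(tru >= c(80, 40, 0.5, 0.5) &
                      tru <= c(100, 100, 10, 6)))
  }
})

test_that("a spec outside the PK envelope is rejected", {
  expect_error(generate_cohort(cohort_spec(2, age_range = c(100, 120),
                                           seed = 1)),
               "envelope")
})

test_that("every virtual patient reaches surgical-depth BIS", {
  cohort <- generate_cohort(cohort_spec(5, seed = 42))
  times <- seq(0, 60, by = 0.25)
  for (m in cohort) {
    b <- simulate_bis(m$patient, m$protocol, m$pd_true, times)
    expect_lt(min(b$bis), 60)
    expect_equal(b$bis[1], m$pd_true$e0) # awake at induction
  }
})

test_that("observation noise has the configured spread and is seeded", {
  m <- generate_cohort(cohort_spec(1, seed = 3))[[1]]
  times <- seq(0, 60, length.out = 2500)
  obs <- observe_bis(m, times, seed = 7)
  expect_identical(obs$bis, observe_bis(m, times, seed = 7)$bis)
  resid <- obs$bis - attr(obs, "noiseless")
  expect_equal(var(resid), m$noise_sd^2, tolerance = 0.2)
  expect_true(all(obs$bis >= 0 & obs$bis <= 100))
})

test_that("zero observation noise returns the simulator output exactly", {
  m <- generate_cohort(cohort_spec(1, seed = 6, noise_sd = 0))[[1]]
  times <- seq(0, 30, by = 0.5)
  obs <- observe_bis(m, times, seed = 1)
  expect_equal(obs$bis, attr(obs, "noiseless"))
})

test_that("feature generation is seeded and carries learnable signal", {
  m <- generate_cohort(cohort_spec(1, seed = 3, noise_sd = 0))[[1]]
  times <- seq(0, 60, by = 0.1)
  fs <- generate_eeg_features(m, times, seed = 11, n_informative = 1,
                              n_distractors = 0, feature_noise_sd = 0)
  expect_identical(fs$features,
                   generate_eeg_features(m, times, seed = 11,
                                         n_informative = 1,
                                         n_distractors = 0,
                                         feature_noise_sd = 0)$features)
  fit <- gbdt_fit(fs$features, fs$target, n_trees = 200, shrinkage = 0.1,
                  max_depth = 3)
  expect_gt(r_squared(fs$target, fitted(fit)), 0.99)
})

test_that("distractor-only features carry no out-of-sample signal", {
  m <- generate_cohort(cohort_spec(1, seed = 4, noise_sd = 3))[[1]]
  tt <- seq(0, 50, length.out = 500)
  fs <- generate_eeg_features(m, tt, seed = 13, n_informative = 0,
                              n_distractors = 3)
  idx <- seq(1, 500, by = 2)
  fit <- gbdt_fit(fs$features[idx, ], fs$target[idx], n_trees = 50,
                  max_depth = 2, min_samples_leaf = 50)
  r2_test <- r_squared(fs$target[-idx], predict(fit, fs$features[-idx, ]))
  expect_lt(abs(r2_test), 0.15)
})
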