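test_that("lean body mass matches the sex-specific formulas", {
  expect_equal(lean_body_mass(60, 160, "female"),
               1.07 * 60 - 148 * 60^2 / 160^2) # 43.3875
  expect_equal(lean_body_mass(60, 160, "female"), 43.3875)
  expect_equal(lean_body_mass(77, 177, "male"),
               1.1 * 77 - 128 * 77^2 / 177^2)
  # tiny weight: linear term dominates, still positive, no error
  expect_gt(lean_body_mass(1e-4, 170, "female"), 0)
  expect_equal(lean_body_mass(1e-4, 170, "female"), 1.07e-4,
               tolerance = 1e-3)
})

test_that("lean body mass rejects degenerate or invalid covariates", {
  expect_error(lean_body_mass(300, 120, "female"), "non-positive")
  expect_error(lean_body_mass(-5, 170, "male"), "positive")
  expect_error(lean_body_mass(60, 160, "other"), "male")
})

test_that("reference covariates return the printed intercepts exactly", {
  pk <- ref_pk()
  expect_identical(pk$V1, 4.27)
  expect_identical(pk$V3, 238)
  expect_identical(pk$Cl3, 0.836)
  expect_equal(pk$V2, 18.9)
  expect_equal(pk$Cl1, 1.89)
  expect_equal(pk$Cl2, 1.29)
  expect_equal(pk$k10, 1.89 / 4.27)
})

test_that("age enters V2 and Cl2 linearly", {
  p73 <- patient("a", 73, 77, 177, "male")
  pk <- pk_params(p73, lbm = 59)
  expect_equal(pk$V2, 18.9 - 0.391 * 20) # 11.08
  expect_equal(pk$Cl2, 1.29 - 0.024 * 20)
})

test_that("rate constants reconstruct the clearances for random patients", {
  set.seed(41)
  for (i in 1:25) {
    p <- patient("x", runif(1, 40, 90), runif(1, 45, 95),
                 runif(1, 150, 190), sample(c("male", "female"), 1))
    pk <- pk_params(p)
    expect_equal(pk$k10 * pk$V1, pk$Cl1, tolerance = 1e-12)
    expect_equal(pk$k12 * pk$V1, pk$Cl2, tolerance = 1e-12)
    expect_equal(pk$k13 * pk$V1, pk$Cl3, tolerance = 1e-12)
    expect_equal(pk$k21 * pk$V2, pk$Cl2, tolerance = 1e-12)
    expect_equal(pk$k31 * pk$V3, pk$Cl3, tolerance = 1e-12)
    expect_true(all(unlist(pk) > 0))
  }
})

test_that("V2 and Cl2 decrease with age; Cl1 increases with weight at fixed lbm", {
  ages <- seq(40, 90, by = 10)
  pks <- lapply(ages, function(a) pk_params(patient("x", a, 77, 177,
                                                    "male"), lbm = 59))
  expect_true(all(diff(sapply(pks, `[[`, "V2")) < 0))
  expect_true(all(diff(sapply(pks, `[[`, "Cl2")) < 0))
  wts <- seq(55, 95, by = 10)
  cl1 <- sapply(wts, function(w)
    pk_params(patient("x", 53, w, 177, "male"), lbm = 59)$Cl1)
  expect_true(all(diff(cl1) > 0))
})

test_that("out-of-range covariates raise an error naming the parameter", {
  # age far beyond the model's envelope drives V2 negative
  expect_error(pk_params(patient("x", 110, 77, 177, "male"), lbm = 59),
               "V2")
})

test_that("cohort CSV round-trips patients", {
  cohort <- list(patient("p01", 70, 62, 165, "female"),
                 patient("p02", 81, 78, 172, "male"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cohort, path)
  back <- read_cohort_csv(path)
  expect_equal(back, cohort)
  expect_error(read_cohort_csv(withr::local_tempfile(lines = "a,b\n1,2",
                                                     fileext = ".csv")),
               "columns")
})

test_that("parameters serialize to flat JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  write_params_json(ref_pk(), path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$V2, 18.9)
  expect_equal(back$k21, 1.29 / 18.9)
})
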