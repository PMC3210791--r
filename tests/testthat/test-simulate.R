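test_that("profile validation catches malformed inputs", {
  expect_error(cohort_profile(0, list(g = c(a = 1))), "n must be")
  expect_error(cohort_profile(10, list(g = c(a = 0.5, b = 0.6))), "sum to 1")
  expect_error(cohort_profile(10, list(g = c(a = 0.5, b = 0.5)),
                              true_beta = -1), "true_beta")
  expect_error(cohort_profile(10, list(g = c(a = 0.5, b = 0.5)),
                              subgroup_shifts = list(g = c(z = 1))),
               "undeclared level")
  expect_error(cohort_profile(10, list(g = c(a = 0.5, b = 0.5)),
                              covariate_effects = list(h = c(a = 1))),
               "undeclared covariate")
})

test_that("same profile and seed give identical cohorts; caller RNG untouched", {
  prof <- basic_profile(300, seed = 7)
  set.seed(99); before <- runif(1)
  a <- simulate_cohort(prof)
  b <- simulate_cohort(prof)
  expect_identical(a$outcome, b$outcome)
  expect_identical(a$prediction, b$prediction)
  expect_identical(as.character(a$marker), as.character(b$marker))
  set.seed(99)
  expect_identical(runif(1), before)
  c <- simulate_cohort(prof, seed = 8)
  expect_false(identical(a$outcome, c$outcome))
})

test_that("empirical level frequencies recover the marginals", {
  prof <- cohort_profile(
    1e5, list(g = c(a = 0.2, b = 0.3, c = 0.5)), seed = 5)
  co <- simulate_cohort(prof)
  freq <- table(co$g) / nrow(co)
  # 5 sigma binomial bounds at n = 1e5
  for (lv in names(prof$covariate_marginals$g)) {
    p <- prof$covariate_marginals$g[[lv]]
    expect_lt(abs(freq[[lv]] - p), 5 * sqrt(p * (1 - p) / 1e5))
  }
})

test_that("calibrated-by-construction profiles recalibrate to (0, 1)", {
  prof <- basic_profile(10000, true_alpha = 0, true_beta = 1, seed = 31)
  fit <- fit_calibration(simulate_cohort(prof))
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$alpha - 0), 3 * se[1])
  expect_lt(abs(fit$beta - 1), 3 * se[2])
})

test_that("a negative subgroup shift depresses observed below predicted survival", {
  prof <- basic_profile(20000, marker_shift = -1.3, seed = 13)
  co <- simulate_cohort(prof)
  shifted <- co[co$marker == "high", ]
  expect_gt(mean(shifted$prediction) - mean(shifted$outcome), 0.05)
  unshifted <- co[co$marker == "low", ]
  expect_lt(abs(mean(unshifted$prediction) - mean(unshifted$outcome)), 0.02)
})

test_that("quadrature expectations agree with large-sample simulation", {
  prof <- cohort_profile(
    2e5, list(g = c(a = 0.3, b = 0.7)),
    risk_mean = 1.2, risk_sd = 0.8, true_alpha = -0.4, true_beta = 1.3,
    subgroup_shifts = list(g = c(b = -0.9)),
    covariate_effects = list(g = c(a = 0.4)), seed = 77)
  co <- simulate_cohort(prof)
  expect_equal(mean(co$prediction), expected_prediction(prof),
               tolerance = 0.005)
  expect_equal(mean(co$outcome), expected_survival(prof),
               tolerance = 0.005)
})

test_that("calibrate_profile hits its targets in expectation", {
  prof <- calibrate_profile(basic_profile(100, marker_effect = 0.8),
                            target_prediction = 0.75,
                            target_survival = 0.6)
  expect_equal(expected_prediction(prof), 0.75, tolerance = 1e-6)
  expect_equal(expected_survival(prof), 0.6, tolerance = 1e-6)
})

test_that("built-in profiles encode the published cohort structure", {
  prof <- builtin_profiles()
  expect_equal(prof$french$covariate_marginals$her2[["positive"]],
               23 / 435)
  expect_equal(prof$french$n, 435L)
  expect_equal(prof$dutch$n, 247L)
  expect_equal(prof$dutch$covariate_marginals$age[["<40"]], 57 / 247)
  for (p in prof) {
    for (f in p$covariate_marginals) expect_equal(sum(f), 1)
  }
  # solved, not tuned: expectations match the published targets
  expect_equal(expected_prediction(prof$french), 0.851, tolerance = 1e-6)
  expect_equal(expected_survival(prof$french), 0.874, tolerance = 1e-6)
  expect_equal(expected_prediction(prof$dutch), 0.786, tolerance = 1e-6)
  expect_equal(expected_survival(prof$dutch), 0.664, tolerance = 1e-6)
})

test_that("default-seed french cohort lands in the stochastic band of its target", {
  co <- simulate_cohort(builtin_profiles()$french)
  # binomial SE at n = 435 is about 1.6 percentage points
  expect_lt(abs(mean(co$outcome) - 0.874), 4 * sqrt(0.874 * 0.126 / 435))
})

test_that("profiles round trip through the JSON config format", {
  prof <- basic_profile(50, marker_effect = 0.7, marker_shift = -0.2,
                        seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_profile(prof, path)
  back <- read_profile(path)
  expect_equal(back$covariate_marginals, prof$covariate_marginals)
  expect_equal(back$true_alpha, prof$true_alpha)
  expect_equal(back$subgroup_shifts$marker, prof$subgroup_shifts$marker)
  expect_identical(simulate_cohort(back)$outcome,
                   simulate_cohort(prof)$outcome)
})
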