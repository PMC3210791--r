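test_that("a saturated two-point design recalibrates exactly to (0, 1)", {
  fit <- fit_calibration(two_point_cohort(survivors = c(1, 4)))
  expect_true(fit$estimable)
  expect_equal(fit$alpha, 0, tolerance = 1e-6)
  expect_equal(fit$beta, 1, tolerance = 1e-6)
  expect_equal(fit$statistic, 0, tolerance = 1e-9)
  expect_equal(fit$p_value, 1, tolerance = 1e-9)
  # Wald statistic agrees at the null point
  fw <- fit_calibration(two_point_cohort(c(1, 4)), test = "wald")
  expect_equal(fw$statistic, 0, tolerance = 1e-9)
})

test_that("separation and single-class subgroups are flagged, not fabricated", {
  sep <- fit_calibration(two_point_cohort(survivors = c(0, 5)))
  expect_false(sep$estimable)
  expect_true(is.na(sep$p_value))

  one_class <- as_cohort(data.frame(outcome = 1, prediction = c(0.4, 0.8),
                                    marker = "low"), simple_schema())
  fit <- fit_calibration(one_class)
  expect_false(fit$estimable)
  expect_true(is.na(fit$p_value))
})

test_that("recalibration recovers known miscalibration parameters", {
  prof <- basic_profile(5000, true_alpha = 0.5, true_beta = 0.7,
                        risk_mean = 0, risk_sd = 1.2, seed = 21)
  fit <- fit_calibration(simulate_cohort(prof))
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$alpha - 0.5), 3 * se[1])
  expect_lt(abs(fit$beta - 0.7), 3 * se[2])
  # intercept-only variant frees alpha with the slope pinned at 1
  fit1 <- fit_calibration(simulate_cohort(prof), hypothesis = "intercept")
  expect_equal(fit1$beta, 1)
  expect_equal(fit1$df, 1L)
})

test_that("agreement table reproduces means, differences and empty rows", {
  co <- simulate_cohort(basic_profile(500, marker_shift = -1, seed = 4))
  tab <- agreement_table(co, by = "marker")
  all_row <- tab[tab$covariate == "all", ]
  expect_equal(all_row$difference,
               -100 * mean(co$outcome - co$prediction), tolerance = 1e-12)
  expect_equal(all_row$n, 500L)
  expect_equal(tab$n[-1], as.vector(table(co$marker)))
  # injected shift shows as over-optimism confined to the shifted level
  expect_gt(tab$difference[tab$level == "high"],
            tab$difference[tab$level == "low"])

  # structurally empty level yields an n = 0 row with missing statistics
  fr <- simulate_cohort(builtin_profiles()$french, seed = 2)
  tr <- agreement_table(fr, by = "treatment")
  both <- tr[tr$level == "both", ]
  expect_equal(both$n, 0L)
  expect_true(all(is.na(c(both$predicted, both$observed, both$p_value))))
})

test_that("prediction bins tile the unit interval and preserve counts", {
  co <- simulate_cohort(basic_profile(2000, seed = 6))
  bins <- bin_predictions(co, width = 0.05, keep_empty = TRUE)
  expect_equal(nrow(bins), 20)
  expect_equal(bins$lower, seq(0, 0.95, by = 0.05))
  expect_equal(sum(bins$n), nrow(co))

  point <- as_cohort(data.frame(outcome = c(1, 0, 1), prediction = 0.87,
                                marker = "low"), simple_schema())
  pb <- bin_predictions(point)
  expect_equal(nrow(pb), 1)
  expect_equal(pb$lower, 0.85)
  expect_equal(pb$mean_predicted, 0.87)

  # boundary p = 1 folds into the final bin
  edge <- as_cohort(data.frame(outcome = c(1, 0), prediction = c(1, 0.999),
                               marker = "low"), simple_schema())
  eb <- bin_predictions(edge)
  expect_equal(nrow(eb), 1)
  expect_equal(eb$n, 2)
})

test_that("uniform predictions spread roughly evenly over 20 bins", {
  prof <- cohort_profile(1e5, list(g = c(a = 1)), risk_mean = 0,
                         risk_sd = 1, seed = 9)
  co <- simulate_cohort(prof)
  co$prediction <- withr::with_seed(123, runif(1e5))
  bins <- bin_predictions(co, width = 0.05, keep_empty = TRUE)
  expect_equal(nrow(bins), 20)
  expect_true(all(abs(bins$n / 1e5 - 0.05) < 0.005))
})

test_that("rejection rate grows with the true intercept miscalibration", {
  rate <- function(a) {
    mean(vapply(1:250, function(r) {
      prof <- cohort_profile(435, list(marker = c(low = 0.5, high = 0.5)),
                             risk_mean = 1.5, risk_sd = 0.9,
                             true_alpha = a, seed = 7000 * a + r)
      fit_calibration(simulate_cohort(prof))$p_value < 0.05
    }, logical(1)))
  }
  rates <- vapply(c(0, 0.5, 1), rate, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.5)
})

test_that("binned points of a calibrated cohort track the identity line", {
  co <- simulate_cohort(basic_profile(50000, seed = 15))
  bins <- bin_predictions(co, width = 0.05)
  busy <- bins[bins$n >= 200, ]
  ls <- stats::lm(observed ~ mean_predicted, data = busy,
                  weights = busy$n)
  slope <- coef(ls)[2]
  se <- sqrt(diag(vcov(ls)))[2]
  expect_lt(abs(slope - 1), 3 * se)
})
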