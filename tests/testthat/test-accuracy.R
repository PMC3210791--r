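test_that("predictive inaccuracy matches direct arithmetic and its closed form", {
  expect_equal(predictive_inaccuracy(c(1, 0), c(1, 0)), 0)
  expect_equal(predictive_inaccuracy(c(1, 0, 1), c(0.8, 0.3, 0.6)), 0.3)
  expect_error(predictive_inaccuracy(c(1, 0), 0.5), "length")
  # constant predictor at the outcome mean: PI = 2 m (1 - m)
  withr::with_seed(88, {
    for (r in 1:20) {
      y <- rbinom(30 + r, 1, runif(1, 0.2, 0.8))
      m <- mean(y)
      if (m == 0 || m == 1) next
      expect_equal(predictive_inaccuracy(y, rep(m, length(y))),
                   2 * m * (1 - m), tolerance = 1e-12)
    }
  })
})

test_that("explained variation reproduces reference inaccuracy reductions", {
  # frozen published PI pairs; printed EVs were 3.3 and 2.4
  expect_equal(round(explained_variation(0.212, 0.205), 1), 3.3)
  expect_equal(round(explained_variation(0.212, 0.207), 1), 2.4)
  expect_equal(explained_variation(0.4, 0.4), 0)
  expect_lt(explained_variation(0.393, 0.396), 0)  # worse model, negative EV
  expect_error(explained_variation(0, 0.1), "positive")
})

test_that("rank-based AUC equals the brute-force pairwise oracle", {
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(auc(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)
  expect_equal(auc(c(1, 1, 0), c(0.9, 0.4, 0.6))$auc, 0.5)
  withr::with_seed(17, {
    for (r in 1:50) {
      n <- sample(10:200, 1)
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
      expect_equal(auc(y, s)$auc, auc_bruteforce(y, s), tolerance = 1e-12)
    }
  })
})

test_that("AUC is invariant under strictly increasing transforms", {
  withr::with_seed(18, {
    y <- rbinom(150, 1, 0.4)
    s <- rnorm(150)
    a <- auc(y, s)
    expect_equal(auc(y, exp(s))$auc, a$auc, tolerance = 1e-12)
    expect_equal(auc(y, qlogis(plogis(s)))$auc, a$auc, tolerance = 1e-9)
  })
})

test_that("AUC interval matches the independent DeLong implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(19, {
    y <- rbinom(200, 1, 0.6)
    s <- rnorm(200) + y
  })
  ours <- auc(y, s)
  ref <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(ours$ci, ci[c(1, 3)], tolerance = 1e-6)
})

test_that("single-class outcomes yield a flagged, missing AUC", {
  a <- auc(c(1, 1, 1), c(0.2, 0.5, 0.9))
  expect_false(a$estimable)
  expect_true(is.na(a$auc))
})

test_that("bootstrap SEs are deterministic and vanish on degenerate cohorts", {
  co <- simulate_cohort(basic_profile(250, marker_effect = 0.8, seed = 61))
  cfg <- bootstrap_config(B = 50, seed = 5)
  se1 <- bootstrap_se(co, "marker", "pi", cfg)
  se2 <- bootstrap_se(co, "marker", "pi", cfg)
  expect_identical(as.numeric(se1), as.numeric(se2))
  expect_true(attr(se1, "reliable"))

  # perfect predictions: every resample refits to (near) zero inaccuracy,
  # so the statistic is constant and its SE vanishes
  perfect <- as_cohort(data.frame(outcome = rep(c(1, 0), 25),
                                  prediction = rep(c(1, 0), 25),
                                  marker = rep(c("low", "high"), 25)),
                       simple_schema())
  se0 <- bootstrap_se(perfect, character(0), "pi", bootstrap_config(20, 1))
  expect_lt(as.numeric(se0), 1e-6)
})

test_that("offset-only bootstrap SE has the expected magnitude on the french profile", {
  co <- simulate_cohort(builtin_profiles()$french, seed = 12)
  se <- bootstrap_se(co, character(0), "pi", bootstrap_config(200, 7))
  expect_gt(as.numeric(se), 0.005)
  expect_lt(as.numeric(se), 0.06)
})

test_that("accuracy table: uninformative covariates add nothing, real ones do", {
  co <- simulate_cohort(basic_profile(600, marker_effect = 1.5, seed = 62))
  co$flat <- factor(rep(c("x", "y"), length.out = nrow(co)))
  sch <- cohort_schema(list(marker = c("low", "high"), flat = c("x", "y")))
  df <- data.frame(outcome = co$outcome, prediction = co$prediction,
                   marker = as.character(co$marker),
                   flat = as.character(co$flat))
  co2 <- as_cohort(df, sch)
  tab <- accuracy_table(co2, c("flat", "marker"),
                        bootstrap_config(B = 60, seed = 6))
  expect_equal(tab$model[1], "Model without predictors")
  expect_true(is.na(tab$ev[1]))
  expect_lt(abs(tab$ev[tab$model == "Model with flat"]), 1.5)
  expect_gt(tab$ev[tab$model == "Model with marker"], 2)
  expect_gt(tab$auc[tab$model == "Model with marker"], tab$auc[1])
  expect_true(all(tab$auc_low <= tab$auc & tab$auc <= tab$auc_high))
})

test_that("offset-only fitted probabilities rank patients like the raw prediction", {
  co <- simulate_cohort(basic_profile(4000, seed = 63))
  tab <- accuracy_table(co, character(0), bootstrap_config(B = 10, seed = 2))
  expect_equal(tab$auc[1], auc(co$outcome, co$prediction)$auc,
               tolerance = 1e-12)
})
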