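# Shared fixture builders; everything is generated in code.

simple_schema <- function() {
  cohort_schema(list(marker = c("low", "high")))
}

# a tiny hand-built cohort
simple_cohort <- function(outcome = c(1, 0, 1),
                          prediction = c(0.9, 0.5, 0.7),
                          marker = c("low", "high", "low")) {
  as_cohort(data.frame(outcome = outcome, prediction = prediction,
                       marker = marker),
            simple_schema(), label = "tiny")
}

# saturated two-point design: the fitted recalibration curve must pass
# through the observed proportions, which equal the predictions exactly
two_point_cohort <- function(survivors = c(1, 4)) {
  as_cohort(data.frame(
    outcome = c(rep(1, survivors[1]), rep(0, 5 - survivors[1]),
                rep(1, survivors[2]), rep(0, 5 - survivors[2])),
    prediction = c(rep(0.2, 5), rep(0.8, 5)),
    marker = "low"),
    simple_schema(), label = "two-point")
}

# cohort whose mean predicted / observed survival (in percent) are exact
percent_cohort <- function(pred_pct, obs_pct, n = 1000) {
  k <- round(n * obs_pct / 100)
  stopifnot(k == n * obs_pct / 100)  # exact by construction
  as_cohort(data.frame(outcome = c(rep(1, k), rep(0, n - k)),
                       prediction = pred_pct / 100,
                       marker = "low"),
            simple_schema(), label = "percent")
}

# minimal profile: one binary covariate, optional effect on the outcome
basic_profile <- function(n, true_alpha = 0, true_beta = 1,
                          marker_effect = 0, marker_shift = 0,
                          risk_mean = 1, risk_sd = 1, seed = 1L) {
  cohort_profile(
    n = n,
    covariate_marginals = list(marker = c(low = 0.5, high = 0.5)),
    risk_mean = risk_mean, risk_sd = risk_sd,
    true_alpha = true_alpha, true_beta = true_beta,
    covariate_effects = if (marker_effect != 0)
      list(marker = c(high = marker_effect)) else list(),
    subgroup_shifts = if (marker_shift != 0)
      list(marker = c(high = marker_shift)) else list(),
    seed = seed)
}

# brute-force pairwise AUC oracle: mean over all positive x negative
# pairs, ties counted one half
auc_bruteforce <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
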