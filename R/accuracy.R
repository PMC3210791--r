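#' Predictive inaccuracy
#'
#' The mean absolute difference between the observed binary outcomes and
#' a model's fitted probabilities; 0 for a perfect 0/1 predictor, and
#' \eqn{2m(1-m)} for the constant predictor at the outcome mean `m`.
#' Lower is better.
#'
#' @param outcomes Binary 0/1 vector.
#' @param fitted Probability vector of the same length, values in `[0, 1]`.
#' @return A single number in `[0, 1]`.
#' @examples
#' predictive_inaccuracy(c(1, 0, 1), c(0.8, 0.3, 0.6)) # 0.3
#' @export
predictive_inaccuracy <- function(outcomes, fitted) {
  if (length(outcomes) != length(fitted)) {
    stop("outcomes and fitted must have the same length", call. = FALSE)
  }
  if (length(outcomes) < 1) stop("empty input", call. = FALSE)
  if (any(!outcomes %in% c(0, 1))) stop("outcomes must be 0/1", call. = FALSE)
  if (any(fitted < 0 | fitted > 1)) {
    stop("fitted probabilities must lie in [0, 1]", call. = FALSE)
  }
  mean(abs(outcomes - fitted))
}

#' Explained variation from a pair of predictive inaccuracies
#'
#' The proportional reduction in predictive inaccuracy achieved by a model
#' relative to a reference model, expressed in percent:
#' \deqn{EV = 100 (PI_{ref} - PI_{model}) / PI_{ref}.}
#' An R-squared-like measure for binary outcomes; negative values are
#' possible when the richer model fits worse out of penalty-free chance.
#'
#' @param pi_null PI of the reference model (must be positive).
#' @param pi_model PI of the candidate model.
#' @return Explained variation in percent.
#' @examples
#' explained_variation(0.212, 0.205) # about 3.3
#' @export
explained_variation <- function(pi_null, pi_model) {
  if (!is.finite(pi_null) || pi_null <= 0) {
    stop("reference predictive inaccuracy must be positive", call. = FALSE)
  }
  100 * (pi_null - pi_model) / pi_null
}

#' Area under the ROC curve with an asymptotic confidence interval
#'
#' Rank-based (Wilcoxon-Mann-Whitney) AUC: the probability that a
#' randomly chosen surviving patient receives a higher score than a
#' randomly chosen non-survivor, ties counted one half. The confidence
#' interval uses the DeLong asymptotic variance from per-observation
#' placement values.
#'
#' @param outcomes Binary 0/1 vector with both classes present.
#' @param scores Numeric score vector (higher = more likely outcome 1).
#' @param conf_level Confidence level, default 0.95.
#' @return Object of class `auc_estimate`: `auc`, `se`, `ci` (length-2,
#'   truncated to `[0, 1]`), `n_pos`, `n_neg`. Single-class input returns
#'   `auc = NA` flagged via `estimable = FALSE`.
#' @examples
#' auc(c(1, 1, 0), c(0.9, 0.4, 0.6))
#' @export
auc <- function(outcomes, scores, conf_level = 0.95) {
  if (length(outcomes) != length(scores)) {
    stop("outcomes and scores must have the same length", call. = FALSE)
  }
  if (any(!outcomes %in% c(0, 1))) stop("outcomes must be 0/1", call. = FALSE)
  pos <- outcomes == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    return(structure(list(auc = NA_real_, se = NA_real_,
                          ci = c(NA_real_, NA_real_), n_pos = n1,
                          n_neg = n0, conf_level = conf_level,
                          estimable = FALSE),
                     class = "auc_estimate"))
  }
  r <- rank(scores, ties.method = "average")
  a <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # DeLong variance from placement values: midranks within each class
  r1 <- rank(scores[pos], ties.method = "average")
  r0 <- rank(scores[!pos], ties.method = "average")
  v10 <- (r[pos] - r1) / n0          # P(score0 < score1) + tie/2, per positive
  v01 <- 1 - (r[!pos] - r0) / n1     # per negative
  var_a <- stats::var(v10) / n1 + stats::var(v01) / n0
  se <- sqrt(var_a)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(a + c(-1, 1) * z * se, 0), 1)
  structure(list(auc = a, se = se, ci = ci, n_pos = n1, n_neg = n0,
                 conf_level = conf_level, estimable = TRUE),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  if (!x$estimable) {
    cat("AUC: non-estimable (single outcome class)\n")
    return(invisible(x))
  }
  cat(sprintf("AUC %.3f [%.3f;%.3f] (%d positives, %d negatives)\n",
              x$auc, x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Bootstrap configuration
#'
#' @param B Number of case resamples (rows drawn with replacement),
#'   default 200.
#' @param seed RNG seed for the resample draws.
#' @param stratified If `TRUE`, resample survivors and non-survivors
#'   separately, preserving the outcome split.
#' @return Object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(B = 200, seed = 1L, stratified = FALSE) {
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  structure(list(B = as.integer(B), seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "bootstrap_config")
}

# draw B bootstrap index sets for a cohort
.boot_indices <- function(y, cfg) {
  n <- length(y)
  with_local_seed(cfg$seed, {
    lapply(seq_len(cfg$B), function(b) {
      if (cfg$stratified) {
        c(sample(which(y == 1), sum(y == 1), replace = TRUE),
          sample(which(y == 0), sum(y == 0), replace = TRUE))
      } else {
        sample.int(n, n, replace = TRUE)
      }
    })
  })
}

# refit an offset model on a row subset and return fitted probabilities,
# or NULL if the fit fails / does not converge
.refit_pi <- function(cohort, variables, idx, eps = 1e-6) {
  sub <- structure(cohort[idx, , drop = FALSE],
                   schema = attr(cohort, "schema"),
                   label = attr(cohort, "label"),
                   class = c("cohort", "data.frame"))
  fit <- tryCatch(.fit_offset(sub, variables, "multivariate", 0.95, eps),
                  error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  predictive_inaccuracy(sub$outcome, stats::fitted(fit$model))
}

#' Bootstrap standard error of a predictive-accuracy statistic
#'
#' Resamples patients with replacement, refits the offset model(s) on
#' each resample and recomputes the statistic; the SE is the sample SD
#' across resamples. Resamples where a fit fails are dropped and counted;
#' more than 20% failures flags the SE unreliable.
#'
#' @param cohort A `cohort`.
#' @param variables Covariates of the candidate offset model
#'   (`character(0)` for the offset-only model).
#' @param statistic `"pi"` (predictive inaccuracy of the candidate model)
#'   or `"ev"` (explained variation of the candidate versus the
#'   offset-only model, both refit per resample).
#' @param cfg A [bootstrap_config()].
#' @return The SE, with attributes `n_failed`, `reliable` and `values`
#'   (the per-resample statistics).
#' @export
bootstrap_se <- function(cohort, variables, statistic = c("pi", "ev"),
                         cfg = bootstrap_config()) {
  stopifnot(inherits(cohort, "cohort"), inherits(cfg, "bootstrap_config"))
  statistic <- match.arg(statistic)
  idx_sets <- .boot_indices(cohort$outcome, cfg)
  vals <- vapply(idx_sets, function(idx) {
    pim <- .refit_pi(cohort, variables, idx)
    if (is.null(pim)) return(NA_real_)
    if (statistic == "pi") return(pim)
    pi0 <- .refit_pi(cohort, character(0), idx)
    if (is.null(pi0) || pi0 <= 0) return(NA_real_)
    explained_variation(pi0, pim)
  }, numeric(1))
  failed <- sum(is.na(vals))
  se <- stats::sd(vals[!is.na(vals)])
  structure(se, n_failed = failed,
            reliable = failed <= 0.2 * cfg$B, values = vals)
}

#' Predictive-accuracy table for candidate predictors
#'
#' Reproduces the accuracy-gain analysis: an offset-only reference model
#' ("model without predictors"), then one univariate offset model per
#' candidate variable. For each model: in-sample predictive inaccuracy
#' with bootstrap SE, explained variation versus the reference (missing
#' for the reference row) with bootstrap SE, and the AUC of the fitted
#' probabilities with a DeLong confidence interval. All bootstrap
#' statistics reuse one common set of resamples so EV contrasts are
#' computed within resample.
#'
#' @param cohort A `cohort`.
#' @param new_vars Character vector of candidate covariates.
#' @param cfg A [bootstrap_config()].
#' @param conf_level Confidence level for the AUC interval.
#' @return Data frame of class `accuracy_table` with columns `model`,
#'   `pi`, `pi_se`, `ev`, `ev_se`, `auc`, `auc_low`, `auc_high`,
#'   `boot_failed`.
#' @export
accuracy_table <- function(cohort, new_vars, cfg = bootstrap_config(),
                           conf_level = 0.95) {
  stopifnot(inherits(cohort, "cohort"))
  y <- cohort$outcome
  idx_sets <- .boot_indices(y, cfg)
  all_idx <- seq_len(nrow(cohort))

  one_model <- function(variables, label, pi0_boot = NULL) {
    fit <- .fit_offset(cohort, variables, "multivariate", conf_level, 1e-6)
    fitted_p <- stats::fitted(fit$model)
    pi_hat <- predictive_inaccuracy(y, fitted_p)
    pib <- vapply(idx_sets, function(idx) {
      v <- .refit_pi(cohort, variables, idx)
      if (is.null(v)) NA_real_ else v
    }, numeric(1))
    a <- auc(y, fitted_p, conf_level)
    list(label = label, pi = pi_hat, pi_boot = pib, auc = a)
  }

  null_row <- one_model(character(0), "Model without predictors")
  rows <- list(null_row)
  for (v in new_vars) {
    rows[[length(rows) + 1]] <- one_model(v, paste("Model with", v))
  }

  out <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    ok <- !is.na(r$pi_boot)
    if (i == 1) {
      ev <- NA_real_; ev_se <- NA_real_
    } else {
      ev <- explained_variation(null_row$pi, r$pi)
      both <- ok & !is.na(null_row$pi_boot) & null_row$pi_boot > 0
      ev_se <- stats::sd(100 * (null_row$pi_boot[both] - r$pi_boot[both]) /
                           null_row$pi_boot[both])
    }
    data.frame(model = r$label, pi = r$pi,
               pi_se = stats::sd(r$pi_boot[ok]),
               ev = ev, ev_se = ev_se,
               auc = r$auc$auc, auc_low = r$auc$ci[1],
               auc_high = r$auc$ci[2],
               boot_failed = sum(!ok))
  }))
  rownames(out) <- NULL
  structure(out, class = c("accuracy_table", "data.frame"),
            B = cfg$B, seed = cfg$seed)
}

#' @export
print.accuracy_table <- function(x, ...) {
  df <- data.frame(
    model = x$model,
    `PI` = sprintf("%.3f+/-%.3f", x$pi, x$pi_se),
    `EV (%)` = ifelse(is.na(x$ev), "-",
                      sprintf("%.1f+/-%.1f", x$ev, x$ev_se)),
    AUC = sprintf("%.3f [%.3f;%.3f]", x$auc, x$auc_low, x$auc_high),
    check.names = FALSE)
  cat("Accuracy of offset models (prediction logit fixed at 1),",
      attr(x, "B"), "bootstrap resamples\n")
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
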