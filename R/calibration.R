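#' Test calibration of external predictions against observed outcomes
#'
#' Fits the logistic recalibration model
#' \deqn{\mathrm{logit}\, P(Y_i = 1) = \alpha + \beta\, \mathrm{logit}(p_i)}
#' and tests the joint null hypothesis \eqn{(\alpha, \beta) = (0, 1)},
#' under which the external prediction is perfectly calibrated. This
#' regression-based test remains usable at subgroup sizes where grouping
#' patients into near-constant-risk sets would leave the sets too small.
#'
#' The default test statistic is the 2-df likelihood ratio comparing the
#' fitted model with the fully constrained model (prediction logit entered
#' as a pure offset, no free parameters); a Wald version is available.
#' A 1-df "calibration-in-the-large" variant frees only the intercept,
#' holding the slope at 1.
#'
#' Cohorts with a single outcome class, or fits showing separation, are
#' flagged non-estimable and return a missing p-value rather than a
#' fabricated one.
#'
#' @param cohort A `cohort`.
#' @param test `"lr"` (default) or `"wald"` for the joint 2-df test.
#' @param hypothesis `"joint"` tests \eqn{(\alpha,\beta)=(0,1)};
#'   `"intercept"` tests \eqn{\alpha=0} with \eqn{\beta} fixed at 1.
#' @param eps Probability clipping margin, see [clip_prob()].
#' @return An object of class `calibration_fit` with elements `alpha`,
#'   `beta`, `vcov`, `statistic`, `df`, `p_value`, `n`, `events` (deaths),
#'   `estimable`, `test`, `hypothesis`.
#' @examples
#' prof <- cohort_profile(500, list(g = c(a = 0.5, b = 0.5)), seed = 7)
#' fit_calibration(simulate_cohort(prof))
#' @export
fit_calibration <- function(cohort, test = c("lr", "wald"),
                            hypothesis = c("joint", "intercept"),
                            eps = 1e-6) {
  stopifnot(inherits(cohort, "cohort"))
  test <- match.arg(test)
  hypothesis <- match.arg(hypothesis)
  y <- cohort$outcome
  lp <- logit(clip_prob(cohort$prediction, eps))
  n <- length(y)

  out <- structure(list(alpha = NA_real_, beta = NA_real_,
                        vcov = matrix(NA_real_, 2, 2),
                        statistic = NA_real_,
                        df = if (hypothesis == "joint") 2L else 1L,
                        p_value = NA_real_, n = n, events = sum(y == 0),
                        estimable = FALSE, converged = FALSE,
                        test = test, hypothesis = hypothesis),
                   class = "calibration_fit")
  if (n < 2 || length(unique(y)) < 2) return(out)

  # log-likelihood of the fully constrained model logit = lp
  ll_fixed <- sum(y * lp - log1p(exp(lp)))

  if (hypothesis == "joint") {
    fit <- suppressWarnings(stats::glm(y ~ lp, family = stats::binomial()))
    theta <- stats::coef(fit)
    theta0 <- c(0, 1)
  } else {
    fit <- suppressWarnings(stats::glm(y ~ 1 + offset(lp),
                                       family = stats::binomial()))
    theta <- stats::coef(fit)
    theta0 <- 0
  }
  if (anyNA(theta)) return(out)  # rank-deficient (e.g. constant predictions)
  V <- stats::vcov(fit)
  se <- sqrt(diag(V))
  separated <- !fit$converged || any(!is.finite(se)) || any(se > 25)

  out$alpha <- unname(theta[1])
  out$beta <- if (hypothesis == "joint") unname(theta[2]) else 1
  out$vcov[seq_along(theta), seq_along(theta)] <- V
  out$converged <- fit$converged
  if (separated) return(out)
  out$estimable <- TRUE

  if (test == "lr") {
    ll_fit <- as.numeric(stats::logLik(fit))
    out$statistic <- max(0, 2 * (ll_fit - ll_fixed))
  } else {
    d <- theta - theta0
    out$statistic <- as.numeric(d %*% solve(V, d))
  }
  out$p_value <- stats::pchisq(out$statistic, df = out$df,
                               lower.tail = FALSE)
  out
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("Calibration of external predictions (n = ", x$n, ", deaths = ",
      x$events, ")\n", sep = "")
  if (!x$estimable) {
    cat("  non-estimable (single outcome class or separation)\n")
    return(invisible(x))
  }
  cat(sprintf("  intercept alpha = %.4f, slope beta = %.4f\n",
              x$alpha, x$beta))
  h0 <- if (x$hypothesis == "joint") "(alpha, beta) = (0, 1)"
        else "alpha = 0 (slope fixed at 1)"
  cat(sprintf("  %s test of %s: statistic = %.3f (%d df), p = %.4g\n",
              toupper(x$test), h0, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Subgroup agreement between predicted and observed survival
#'
#' For the whole cohort and each level of the requested covariates,
#' tabulates the mean predicted survival, the observed survival (both as
#' percentages), their difference (predicted minus observed; positive
#' values flag over-optimistic predictions), and a calibration p-value
#' from [fit_calibration()] applied within the subgroup. Empty levels
#' yield an n = 0 row with missing statistics.
#'
#' @param cohort A `cohort`.
#' @param by Character vector of covariate names; defaults to all schema
#'   covariates.
#' @param test,hypothesis Passed to [fit_calibration()] for the subgroup
#'   p-values.
#' @return A data frame of class `agreement_table` with columns
#'   `covariate`, `level`, `n`, `predicted`, `observed`, `difference`,
#'   `p_value`. Values are unrounded; the print method rounds percentages
#'   to one decimal.
#' @export
agreement_table <- function(cohort, by = NULL, test = "lr",
                            hypothesis = "joint") {
  stopifnot(inherits(cohort, "cohort"))
  sch <- attr(cohort, "schema")
  if (is.null(by)) by <- names(sch$covariates)
  unknown <- setdiff(by, names(sch$covariates))
  if (length(unknown)) {
    stop("unknown covariate(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  specs <- list(subgroup_spec("all"))
  for (cv in by) {
    for (lv in levels(cohort[[cv]])) {
      # keep table rows in schema display order, not reference-first order
      specs <- c(specs, list(subgroup_spec(cv, lv)))
    }
  }
  rows <- lapply(specs, function(sp) {
    sel <- resolve_subgroup(cohort, sp, allow_empty = TRUE)
    n <- sum(sel)
    if (n == 0) {
      return(data.frame(covariate = sp$covariate,
                        level = sp$level %||% "all", n = 0L,
                        predicted = NA_real_, observed = NA_real_,
                        difference = NA_real_, p_value = NA_real_))
    }
    sub <- cohort[sel, , drop = FALSE]
    pred <- 100 * mean(sub$prediction)
    obs <- 100 * mean(sub$outcome)
    cal <- fit_calibration(
      structure(sub, schema = sch, label = attr(cohort, "label"),
                class = c("cohort", "data.frame")),
      test = test, hypothesis = hypothesis)
    data.frame(covariate = sp$covariate, level = sp$level %||% "all",
               n = as.integer(n), predicted = pred, observed = obs,
               difference = pred - obs, p_value = cal$p_value)
  })
  res <- do.call(rbind, rows)
  # restore schema display order of levels within each covariate
  ord <- unlist(lapply(unique(res$covariate), function(cv) {
    idx <- which(res$covariate == cv)
    if (cv == "all") return(idx)
    idx[order(match(res$level[idx], c(sch$covariates[[cv]], "missing")))]
  }))
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("agreement_table", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.agreement_table <- function(x, digits = 1, ...) {
  df <- as.data.frame(x)
  for (cl in c("predicted", "observed", "difference")) {
    df[[cl]] <- round(df[[cl]], digits)
  }
  df$p_value <- ifelse(is.na(df$p_value), "",
                       ifelse(df$p_value < 0.01, "<0.01",
                              sprintf("%.2f", df$p_value)))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Bin predictions for a calibration plot
#'
#' Divides the prediction range into fixed-width intervals
#' (default 5%), returning per-bin mean predicted and observed survival
#' fractions — the data behind a predicted-versus-observed calibration
#' plot where perfect agreement falls on the identity line. Intervals are
#' half-open `[k w, (k+1) w)` with the final interval closed at 1.
#'
#' @param cohort A `cohort`.
#' @param width Bin width in probability units, in (0, 1].
#' @param keep_empty Keep empty bins (count 0) instead of dropping them.
#' @return Data frame of class `calibration_bins` with columns `lower`,
#'   `upper`, `n`, `mean_predicted`, `observed`.
#' @export
bin_predictions <- function(cohort, width = 0.05, keep_empty = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  if (width <= 0 || width > 1) stop("width must be in (0, 1]", call. = FALSE)
  p <- cohort$prediction
  y <- cohort$outcome
  k <- ceiling(1 / width)
  idx <- pmin(floor(p / width), k - 1) + 1L  # p = 1 folds into last bin
  rows <- lapply(seq_len(k), function(b) {
    sel <- idx == b
    data.frame(lower = (b - 1) * width, upper = min(b * width, 1),
               n = sum(sel),
               mean_predicted = if (any(sel)) mean(p[sel]) else NA_real_,
               observed = if (any(sel)) mean(y[sel]) else NA_real_)
  })
  res <- do.call(rbind, rows)
  if (!keep_empty) res <- res[res$n > 0, , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("calibration_bins", "data.frame"))
}
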