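#' Added prognostic value via offset logistic regression
#'
#' Fits logistic models of the form
#' \deqn{\mathrm{logit}\, P(Y_i = 1) = \alpha + \beta X_i + \mathrm{logit}(p_i)}
#' where the external prediction enters through its logit with the
#' coefficient fixed at 1 (an offset), so the prediction's own prognostic
#' content is taken as given and only departures from it are estimated.
#'
#' Two modes mirror the two scientific questions:
#' * `"multivariate"` — all variables together. For predictors the
#'   external model already uses: a significant coefficient flags that the
#'   predictor-outcome association in the validation population differs
#'   from the population the model was built on.
#' * `"univariate"` — one model per variable. For candidate predictors
#'   the external model does not use: a significant coefficient means the
#'   predictor adds prognostic information beyond the prediction.
#'
#' Levels with no observations (structural zeros of the cohort) are
#' dropped and recorded; a variable left with a single observed level is
#' an error naming the variable. Per-level separation is flagged and that
#' level's CI reported missing. Each variable receives a single
#' factor-level likelihood-ratio p-value (df = number of non-reference
#' levels) rather than per-level Wald p's.
#'
#' @param cohort A `cohort`.
#' @param variables Character vector of covariate names.
#' @param mode `"multivariate"` or `"univariate"`.
#' @param conf_level Confidence level for Wald odds-ratio intervals.
#' @param eps Probability clipping margin.
#' @return For `"multivariate"`, an `offset_fit`; for `"univariate"`, a
#'   named list of `offset_fit` (class `offset_fit_list`), one per
#'   variable. An `offset_fit` carries `coefficients` (per-level
#'   data frame: `variable`, `level`, `estimate`, `se`, `or`, `or_low`,
#'   `or_high`, `estimable`), `factor_tests` (per-variable LR statistic,
#'   df, p), `alpha` (intercept), `loglik`, `n`, `mode`,
#'   `dropped_levels`, `converged`.
#' @export
fit_offset_model <- function(cohort, variables,
                             mode = c("multivariate", "univariate"),
                             conf_level = 0.95, eps = 1e-6) {
  stopifnot(inherits(cohort, "cohort"))
  mode <- match.arg(mode)
  sch <- attr(cohort, "schema")
  unknown <- setdiff(variables, names(sch$covariates))
  if (length(unknown)) {
    stop("unknown covariate(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (mode == "univariate") {
    fits <- lapply(variables, function(v) {
      .fit_offset(cohort, v, "univariate", conf_level, eps)
    })
    names(fits) <- variables
    return(structure(fits, class = "offset_fit_list"))
  }
  .fit_offset(cohort, variables, "multivariate", conf_level, eps)
}

.fit_offset <- function(cohort, variables, mode, conf_level, eps) {
  y <- cohort$outcome
  lp <- logit(clip_prob(cohort$prediction, eps))
  dat <- data.frame(.y = y, .lp = lp)
  dropped <- list()
  for (v in variables) {
    col <- droplevels(cohort[[v]])
    gone <- setdiff(levels(cohort[[v]]), levels(col))
    if (length(gone)) dropped[[v]] <- gone
    if (nlevels(col) < 2) {
      stop("variable '", v, "' has a single observed level", call. = FALSE)
    }
    dat[[v]] <- col
  }
  form <- stats::reformulate(c(variables, "offset(.lp)"), response = ".y")
  fit <- suppressWarnings(stats::glm(form, data = dat,
                                     family = stats::binomial()))
  V <- stats::vcov(fit)
  cf <- stats::coef(fit)
  se <- sqrt(diag(V))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  # per-level coefficient table, reference rows included with OR fixed at 1
  coef_rows <- list()
  for (v in variables) {
    lev <- levels(dat[[v]])
    for (i in seq_along(lev)) {
      if (i == 1) {
        coef_rows[[length(coef_rows) + 1]] <- data.frame(
          variable = v, level = lev[1], estimate = 0, se = 0,
          or = 1, or_low = NA_real_, or_high = NA_real_, estimable = TRUE)
      } else {
        nm <- paste0(v, lev[i])
        b <- unname(cf[nm]); s <- unname(se[nm])
        ok <- is.finite(b) && is.finite(s) && s <= 25
        coef_rows[[length(coef_rows) + 1]] <- data.frame(
          variable = v, level = lev[i], estimate = b, se = s,
          or = exp(b),
          or_low = if (ok) exp(b - z * s) else NA_real_,
          or_high = if (ok) exp(b + z * s) else NA_real_,
          estimable = ok)
      }
    }
  }
  coefs <- do.call(rbind, coef_rows)

  # factor-level LR tests: drop each variable, keep offset
  ll_full <- as.numeric(stats::logLik(fit))
  ft <- lapply(variables, function(v) {
    rest <- setdiff(variables, v)
    form0 <- stats::reformulate(c(rest, "offset(.lp)"), response = ".y")
    fit0 <- suppressWarnings(stats::glm(form0, data = dat,
                                        family = stats::binomial()))
    df <- nlevels(dat[[v]]) - 1L
    stat <- max(0, 2 * (ll_full - as.numeric(stats::logLik(fit0))))
    data.frame(variable = v, statistic = stat, df = df,
               p_value = stats::pchisq(stat, df, lower.tail = FALSE))
  })

  structure(list(coefficients = coefs,
                 factor_tests = do.call(rbind, ft),
                 alpha = unname(cf["(Intercept)"]),
                 loglik = ll_full,
                 df = length(cf),
                 n = nrow(dat),
                 mode = mode,
                 variables = variables,
                 conf_level = conf_level,
                 dropped_levels = dropped,
                 converged = fit$converged,
                 model = fit),
            class = "offset_fit")
}

#' @export
print.offset_fit <- function(x, ...) {
  what <- if (x$mode == "multivariate") {
    "multivariate (association differs from development population if significant)"
  } else {
    "univariate (adds information beyond the prediction if significant)"
  }
  cat("Offset logistic model, ", what, "\n", sep = "")
  cat("  prediction logit held at coefficient 1; n = ", x$n, "\n", sep = "")
  tab <- x$coefficients
  tab$ci <- ifelse(is.na(tab$or_low), "",
                   sprintf("[%.2f; %.2f]", tab$or_low, tab$or_high))
  p <- x$factor_tests$p_value[match(tab$variable, x$factor_tests$variable)]
  first <- !duplicated(tab$variable)
  tab$p <- ifelse(first, ifelse(p < 0.01, "<0.01", sprintf("%.2f", p)), "")
  print.data.frame(data.frame(variable = ifelse(first, tab$variable, ""),
                              level = tab$level, OR = round(tab$or, 2),
                              `CI 95%` = tab$ci, P = tab$p,
                              check.names = FALSE), row.names = FALSE)
  if (length(x$dropped_levels)) {
    cat("  dropped empty level(s):",
        paste(vapply(names(x$dropped_levels), function(v)
          paste0(v, ": ", paste(x$dropped_levels[[v]], collapse = ", ")),
          character(1)), collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
print.offset_fit_list <- function(x, ...) {
  for (f in x) { print(f); cat("\n") }
  invisible(x)
}

#' Likelihood-ratio p-value between nested offset models
#'
#' Compares a full offset model with a reduced one (same cohort, same
#' offset, a subset of the variables), returning the LR p-value on
#' the difference in model dimension. Identical models give p = 1.
#'
#' @param full,reduced `offset_fit` objects from [fit_offset_model()].
#' @return The p-value, with attributes `statistic` and `df`.
#' @export
factor_p_value <- function(full, reduced) {
  stopifnot(inherits(full, "offset_fit"), inherits(reduced, "offset_fit"))
  if (full$n != reduced$n || !all(reduced$variables %in% full$variables)) {
    stop("models are not nested on the same cohort", call. = FALSE)
  }
  df <- full$df - reduced$df
  if (df < 0) stop("reduced model has more parameters than the full model",
                   call. = FALSE)
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(p, statistic = stat, df = df)
}
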