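#' Baseline characteristics summary
#'
#' Per-covariate level counts and percentages (one decimal in the print
#' method), plus mean (SD) for any continuous columns declared in the
#' schema — the usual first table of a validation report.
#'
#' @param cohort A `cohort`.
#' @return Data frame of class `cohort_summary` with columns `covariate`,
#'   `level`, `n`, `percent` (categorical rows) and, for continuous
#'   columns, `mean`/`sd` rows.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  sch <- attr(cohort, "schema")
  n <- nrow(cohort)
  rows <- list(data.frame(covariate = "all", level = "all", n = n,
                          percent = 100, mean = NA_real_, sd = NA_real_))
  for (cv in names(sch$covariates)) {
    col <- cohort[[cv]]
    for (lv in c(sch$covariates[[cv]],
                 if ("missing" %in% levels(col)) "missing")) {
      k <- sum(col == lv)
      rows[[length(rows) + 1]] <- data.frame(
        covariate = cv, level = lv, n = k, percent = 100 * k / n,
        mean = NA_real_, sd = NA_real_)
    }
  }
  for (cv in sch$continuous) {
    x <- cohort[[cv]]
    rows[[length(rows) + 1]] <- data.frame(
      covariate = cv, level = "(continuous)", n = sum(!is.na(x)),
      percent = NA_real_, mean = mean(x, na.rm = TRUE),
      sd = stats::sd(x, na.rm = TRUE))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(res, class = c("cohort_summary", "data.frame"),
            label = attr(cohort, "label"))
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Baseline characteristics:", attr(x, "label"), "\n")
  df <- as.data.frame(x)
  df$value <- ifelse(is.na(df$percent),
                     sprintf("%.1f (%.1f)", df$mean, df$sd),
                     sprintf("%d (%.1f)", df$n, df$percent))
  print.data.frame(df[, c("covariate", "level", "value")],
                   row.names = FALSE)
  invisible(x)
}

#' Pipeline configuration
#'
#' @param adjuvant_vars Covariates the external model already uses
#'   (analysed together in a multivariate offset model).
#' @param new_vars Candidate covariates not used by the external model
#'   (analysed one at a time in univariate offset models and in the
#'   accuracy table).
#' @param alpha Two-sided significance level for flagging.
#' @param bin_width Calibration bin width.
#' @param B Bootstrap resamples for the accuracy table.
#' @param seed Seed for the bootstrap resamples.
#' @param test,hypothesis Calibration test options, see
#'   [fit_calibration()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(adjuvant_vars, new_vars, alpha = 0.05,
                            bin_width = 0.05, B = 200, seed = 1L,
                            test = "lr", hypothesis = "joint") {
  structure(list(adjuvant_vars = adjuvant_vars, new_vars = new_vars,
                 alpha = alpha, bin_width = bin_width, B = as.integer(B),
                 seed = as.integer(seed), test = test,
                 hypothesis = hypothesis),
            class = "pipeline_config")
}

#' Run the full external-validation pipeline
#'
#' Two-stage analysis of one cohort against an external probabilistic
#' prediction: first agreement (overall calibration fit and test,
#' subgroup agreement table, calibration bins), then added value
#' (multivariate offset model for the predictors the external model
#' already uses, univariate offset models and the accuracy table for
#' candidate predictors). Deterministic given cohort, config and seed.
#'
#' Variables with a single observed level (structural zeros, e.g. an
#' all-node-negative cohort) are skipped in the model stages and listed
#' in the report's `skipped` element.
#'
#' @param cohort A `cohort` (or a path to a cohort CSV, in which case
#'   `schema` must be given).
#' @param config A [pipeline_config()].
#' @param schema Required when `cohort` is a file path.
#' @return Object of class `validation_report` with elements `summary`,
#'   `calibration`, `agreement`, `bins`, `offset_multivariate`,
#'   `offset_univariate`, `accuracy`, `skipped`, `meta`.
#' @export
run_pipeline <- function(cohort, config, schema = NULL) {
  if (is.character(cohort)) {
    if (is.null(schema)) stop("schema required when cohort is a path",
                              call. = FALSE)
    cohort <- read_cohort(cohort, schema)
  }
  stopifnot(inherits(cohort, "cohort"), inherits(config, "pipeline_config"))
  sch <- attr(cohort, "schema")

  usable <- function(vars) {
    ok <- vapply(vars, function(v) nlevels(droplevels(cohort[[v]])) >= 2,
                 logical(1))
    if (any(!ok)) {
      warning("skipping single-level variable(s): ",
              paste(vars[!ok], collapse = ", "), call. = FALSE)
    }
    vars[ok]
  }
  adj <- usable(config$adjuvant_vars)
  new <- usable(config$new_vars)
  skipped <- setdiff(c(config$adjuvant_vars, config$new_vars), c(adj, new))

  report <- list(
    summary = summarize_cohort(cohort),
    calibration = fit_calibration(cohort, test = config$test,
                                  hypothesis = config$hypothesis),
    agreement = agreement_table(cohort,
                                by = unique(c(config$adjuvant_vars,
                                              config$new_vars)),
                                test = config$test,
                                hypothesis = config$hypothesis),
    bins = bin_predictions(cohort, width = config$bin_width),
    offset_multivariate = if (length(adj))
      fit_offset_model(cohort, adj, mode = "multivariate") else NULL,
    offset_univariate = if (length(new))
      fit_offset_model(cohort, new, mode = "univariate") else NULL,
    accuracy = if (length(new))
      accuracy_table(cohort, new,
                     cfg = bootstrap_config(B = config$B,
                                            seed = config$seed)) else NULL,
    skipped = skipped,
    meta = list(label = attr(cohort, "label"), n = nrow(cohort),
                seed = config$seed, alpha = config$alpha,
                exclusions = attr(cohort, "exclusions"),
                package_version =
                  as.character(utils::packageVersion("progval")))
  )
  structure(report, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("=== External validation report:", x$meta$label,
      "(n =", paste0(x$meta$n, ")"), "===\n\n")
  print(x$calibration); cat("\n")
  print(x$agreement); cat("\n")
  if (!is.null(x$offset_multivariate)) { print(x$offset_multivariate); cat("\n") }
  if (!is.null(x$offset_univariate)) { print(x$offset_univariate); cat("\n") }
  if (!is.null(x$accuracy)) print(x$accuracy)
  if (length(x$skipped)) {
    cat("skipped single-level variable(s):",
        paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a validation report
#'
#' `report_json()` renders the full report (all unrounded values) as a
#' JSON string; `render_report()` writes the JSON plus one TSV per table
#' surface into a directory. Rendering is a pure function of the report,
#' so the same report always produces byte-identical artifacts.
#'
#' @param report A `validation_report`.
#' @param dir Output directory (created if needed).
#' @return `report_json()` a JSON string; `render_report()` the paths of
#'   the files written, invisibly.
#' @export
report_json <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  strip <- function(x) {
    if (inherits(x, "glm")) return(NULL)
    if (is.list(x)) {
      x <- lapply(x, strip)
      x[!vapply(x, is.null, logical(1))]
    } else x
  }
  payload <- list(
    meta = report$meta,
    summary = as.data.frame(report$summary),
    calibration = strip(unclass(report$calibration)),
    agreement = as.data.frame(report$agreement),
    bins = as.data.frame(report$bins),
    offset_multivariate = strip(unclass(report$offset_multivariate)),
    offset_univariate = if (!is.null(report$offset_univariate))
      lapply(report$offset_univariate, function(f) strip(unclass(f))),
    accuracy = if (!is.null(report$accuracy))
      as.data.frame(report$accuracy),
    skipped = report$skipped
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null",
                   pretty = TRUE)
}

#' @rdname report_json
#' @export
render_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  w <- function(df, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(as.data.frame(df), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <<- c(paths, p)
  }
  w(report$summary, "summary")
  w(report$agreement, "agreement")
  w(report$bins, "bins")
  if (!is.null(report$offset_multivariate)) {
    w(report$offset_multivariate$coefficients, "offset_multivariate")
  }
  if (!is.null(report$offset_univariate)) {
    w(do.call(rbind, lapply(report$offset_univariate,
                            function(f) f$coefficients)),
      "offset_univariate")
  }
  if (!is.null(report$accuracy)) w(report$accuracy, "accuracy")
  jp <- file.path(dir, "report.json")
  writeLines(report_json(report), jp)
  invisible(c(paths, jp))
}
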