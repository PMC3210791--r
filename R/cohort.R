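#' Declare a cohort covariate schema
#'
#' A schema names the categorical covariates of a cohort and, for each,
#' its ordered level set. The first level of each covariate is its
#' reference level unless overridden in `reference`. Category labels are
#' matched case-insensitively after trimming whitespace when reading files.
#'
#' @param covariates Named list; each element a character vector of levels
#'   for one covariate, in display order.
#' @param reference Optional named character vector overriding the
#'   reference level of selected covariates.
#' @param continuous Optional character vector naming additional numeric
#'   columns (e.g. age in years) carried alongside the categorical
#'   covariates and summarised as mean (SD).
#' @return An object of class `cohort_schema`.
#' @examples
#' cohort_schema(list(age = c("<40", ">=40"), er = c("positive", "negative")))
#' @export
cohort_schema <- function(covariates, reference = NULL, continuous = character()) {
  if (!is.list(covariates) || is.null(names(covariates)) ||
      any(!nzchar(names(covariates)))) {
    stop("covariates must be a named list of level vectors", call. = FALSE)
  }
  covariates <- lapply(covariates, as.character)
  bad <- vapply(covariates, function(l) length(l) < 1 || anyDuplicated(l) > 0,
                logical(1))
  if (any(bad)) {
    stop("covariate(s) with empty or duplicated level sets: ",
         paste(names(covariates)[bad], collapse = ", "), call. = FALSE)
  }
  ref <- vapply(covariates, `[`, character(1), 1L)
  if (!is.null(reference)) {
    unknown <- setdiff(names(reference), names(covariates))
    if (length(unknown)) {
      stop("reference given for undeclared covariate(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (nm in names(reference)) {
      if (!reference[[nm]] %in% covariates[[nm]]) {
        stop("reference level '", reference[[nm]], "' not a level of '",
             nm, "'", call. = FALSE)
      }
      ref[[nm]] <- reference[[nm]]
    }
  }
  structure(list(covariates = covariates, reference = ref,
                 continuous = as.character(continuous)),
            class = "cohort_schema")
}

#' @export
print.cohort_schema <- function(x, ...) {
  cat("Cohort schema:", length(x$covariates), "covariate(s)\n")
  for (nm in names(x$covariates)) {
    cat(" ", nm, ": ", paste(x$covariates[[nm]], collapse = " / "),
        "  (ref: ", x$reference[[nm]], ")\n", sep = "")
  }
  if (length(x$continuous)) {
    cat("  continuous:", paste(x$continuous, collapse = ", "), "\n")
  }
  invisible(x)
}

# normalise a label for case/space-insensitive matching
.canon <- function(x) tolower(trimws(as.character(x)))

#' Assemble a validated patient cohort
#'
#' Builds a `cohort` from a data frame holding one row per patient:
#' a binary `outcome` (1 = alive at the prediction horizon, 0 = dead),
#' a `prediction` column with an external model's survival probability,
#' and one column per schema covariate. Rows with missing outcome or
#' prediction are dropped and counted (mirroring patients with unknown
#' follow-up status); missing covariate values become an explicit
#' `"missing"` level so subgroup tables can still be formed per covariate.
#'
#' @param data Data frame with columns `outcome`, `prediction` and the
#'   schema covariates.
#' @param schema A [cohort_schema()].
#' @param label Free-text cohort label.
#' @return An object of class `cohort`: a data frame with factor-coded
#'   covariates and attributes `schema`, `label` and `exclusions`.
#' @export
as_cohort <- function(data, schema, label = "cohort") {
  stopifnot(inherits(schema, "cohort_schema"))
  data <- as.data.frame(data)
  needed <- c("outcome", "prediction", names(schema$covariates),
              schema$continuous)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  keep <- !is.na(data$outcome) & !is.na(data$prediction)
  n_excluded <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  if (nrow(data) == 0) stop("cohort is empty after exclusions", call. = FALSE)

  out <- suppressWarnings(as.numeric(data$outcome))
  if (any(is.na(out)) || any(!out %in% c(0, 1))) {
    bad <- which(is.na(out) | !out %in% c(0, 1))[1]
    stop("outcome must be 0/1; offending row ", bad, call. = FALSE)
  }
  pred <- suppressWarnings(as.numeric(data$prediction))
  if (any(is.na(pred)) || any(pred < 0) || any(pred > 1)) {
    bad <- which(is.na(pred) | pred < 0 | pred > 1)[1]
    stop("prediction must lie in [0, 1]; offending row ", bad, call. = FALSE)
  }

  res <- data.frame(outcome = out, prediction = pred)
  for (nm in names(schema$covariates)) {
    levels <- schema$covariates[[nm]]
    raw <- .canon(data[[nm]])
    idx <- match(raw, .canon(levels))
    has_missing <- anyNA(data[[nm]]) || any(raw == "missing")
    lev_full <- if (has_missing) c(levels, "missing") else levels
    val <- lev_full[ifelse(is.na(data[[nm]]) | raw == "missing",
                           length(lev_full), idx)]
    if (anyNA(val)) {
      bad <- which(is.na(val))[1]
      stop("unknown category '", data[[nm]][bad], "' for covariate '", nm,
           "' (row ", bad, ")", call. = FALSE)
    }
    # reference level first for model coding
    ref <- schema$reference[[nm]]
    res[[nm]] <- factor(val, levels = c(ref, setdiff(lev_full, ref)))
  }
  for (nm in schema$continuous) res[[nm]] <- as.numeric(data[[nm]])

  structure(res, schema = schema, label = label,
            exclusions = c(missing_outcome_or_prediction = n_excluded),
            class = c("cohort", "data.frame"))
}

#' Read a cohort from a delimited text file
#'
#' Expects a comma-separated UTF-8 file with a header row containing
#' `outcome`, `prediction` and one column per schema covariate. See
#' [as_cohort()] for validation and exclusion rules.
#'
#' @inheritParams as_cohort
#' @param path Path to the CSV file.
#' @return A validated `cohort`.
#' @export
read_cohort <- function(path, schema, label = sub("\\.[^.]*$", "", basename(path))) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), fileEncoding = "UTF-8")
  as_cohort(data, schema, label = label)
}

#' Write a cohort to a delimited text file
#'
#' @param cohort A `cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  df <- as.data.frame(cohort)
  df$prediction <- format(df$prediction, digits = 17, scientific = FALSE,
                          trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.cohort <- function(x, ...) {
  sch <- attr(x, "schema")
  cat("Cohort '", attr(x, "label"), "': ", nrow(x), " patients, ",
      sum(x$outcome == 0), " deaths\n", sep = "")
  cat("mean predicted survival ",
      sprintf("%.1f%%", 100 * mean(x$prediction)),
      ", observed ", sprintf("%.1f%%", 100 * mean(x$outcome)), "\n", sep = "")
  cat("covariates:", paste(names(sch$covariates), collapse = ", "), "\n")
  excl <- attr(x, "exclusions")
  if (!is.null(excl) && sum(excl) > 0) {
    cat("excluded upstream:", sum(excl), "record(s) with missing outcome/prediction\n")
  }
  invisible(x)
}

#' Serialize and restore a cohort schema
#'
#' Schemas round-trip through a plain JSON sidecar file declaring the
#' level sets, reference levels and continuous columns, so a cohort CSV
#' can travel with a machine-readable description of its categories.
#'
#' @param schema A [cohort_schema()].
#' @param path File path.
#' @return `read_schema()` returns a `cohort_schema`.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "cohort_schema"))
  jsonlite::write_json(.named_to_list(unclass(schema)), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort_schema(as.list(raw$covariates), reference = unlist(raw$reference),
                continuous = raw$continuous %||% character())
}

#' Specify a patient subgroup
#'
#' A subgroup is either the whole cohort (`covariate = "all"`) or the set
#' of patients at one level of one covariate, mirroring the row structure
#' of subgroup agreement tables.
#'
#' @param covariate Covariate name, or `"all"`.
#' @param level Level label (ignored for `"all"`).
#' @return An object of class `subgroup_spec`.
#' @export
subgroup_spec <- function(covariate, level = NULL) {
  structure(list(covariate = covariate, level = level),
            class = "subgroup_spec")
}

#' Resolve a subgroup to the matching cohort rows
#'
#' @param cohort A `cohort`.
#' @param spec A [subgroup_spec()].
#' @param allow_empty If `FALSE` (default), an empty subgroup is an error;
#'   agreement tables pass `TRUE` to emit an n = 0 row instead.
#' @return Logical vector selecting the subgroup's rows.
#' @export
resolve_subgroup <- function(cohort, spec, allow_empty = FALSE) {
  stopifnot(inherits(cohort, "cohort"), inherits(spec, "subgroup_spec"))
  if (identical(spec$covariate, "all")) return(rep(TRUE, nrow(cohort)))
  sch <- attr(cohort, "schema")
  if (!spec$covariate %in% names(sch$covariates)) {
    stop("unknown covariate '", spec$covariate, "'", call. = FALSE)
  }
  col <- cohort[[spec$covariate]]
  hit <- match(.canon(spec$level), .canon(levels(col)))
  if (is.na(hit)) {
    stop("unknown level '", spec$level, "' for covariate '",
         spec$covariate, "'", call. = FALSE)
  }
  sel <- as.integer(col) == hit
  if (!allow_empty && !any(sel)) {
    stop("subgroup ", spec$covariate, " = ", spec$level, " is empty",
         call. = FALSE)
  }
  sel
}
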