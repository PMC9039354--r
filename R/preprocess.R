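# Preparation steps mirroring the standard ILPD modelling pipeline:
# mean imputation, 0/1 sex encoding, target recoding, min-max normalisation.
#
# Imputation and scaling statistics can be fit on the whole cohort ("faithful"
# to the common oversample/prepare-then-split practice, leakage included) or
# fit on a training fold and applied elsewhere ("safe"); every report records
# which scope was used.

SCALED_COLUMNS <- function() c("age", biomarker_names())

new_preprocess_report <- function(step, fit_scope, imputed_cells = 0L,
                                  imputed_columns = character(),
                                  encoding_used = NULL, scale_params = NULL) {
  structure(list(step = step, fit_scope = fit_scope,
                 imputed_cells = imputed_cells, imputed_columns = imputed_columns,
                 encoding_used = encoding_used, scale_params = scale_params),
            class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("<preprocess_report: %s (fit scope: %s)>\n", x$step, x$fit_scope))
  if (x$step == "impute_mean") {
    cat(sprintf("  imputed cells: %d (%s)\n", x$imputed_cells,
                paste(x$imputed_columns, collapse = ", ")))
  }
  if (!is.null(x$scale_params)) {
    cat("  scale params (min/max):\n"); print(x$scale_params)
  }
  invisible(x)
}

#' Serialise a preprocessing report alongside run outputs
#'
#' @param report a `preprocess_report`.
#' @param path destination text file.
#' @export
write_preprocess_report <- function(report, path) {
  lines <- c(sprintf("step: %s", report$step),
             sprintf("fit_scope: %s", report$fit_scope),
             sprintf("imputed_cells: %d", report$imputed_cells))
  if (length(report$imputed_columns)) {
    lines <- c(lines, sprintf("imputed_columns: %s",
                              paste(report$imputed_columns, collapse = ",")))
  }
  if (!is.null(report$encoding_used)) {
    lines <- c(lines, sprintf("sex_encoding: %s",
                              paste(names(report$encoding_used),
                                    report$encoding_used, sep = "=", collapse = ",")))
  }
  if (!is.null(report$scale_params)) {
    sp <- report$scale_params
    lines <- c(lines, "scale_params:",
               sprintf("  %s: min=%.17g max=%.17g", rownames(sp), sp[, "min"], sp[, "max"]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Mean-impute missing A/G-ratio values
#'
#' Replaces each missing cell by the arithmetic mean of the observed values of
#' that column, computed either on this cohort (`stats = NULL`) or using
#' statistics fit elsewhere (pass a previous report's `fit_stats`, e.g. fit on
#' a training fold in safe mode). Observed values are never touched.
#'
#' @param cohort an unscaled cohort.
#' @param stats optional named numeric vector of column means to use instead of
#'   fitting on `cohort` (training-only scope).
#' @return list with elements `cohort` (imputed flag set) and `report` (a
#'   `preprocess_report`; its `fit_stats` field carries the means used).
#' @export
impute_mean <- function(cohort, stats = NULL) {
  validate_cohort(cohort)
  if (isTRUE(attr(cohort, "scaled"))) stop("impute before scaling, not after")
  fit_scope <- if (is.null(stats)) "whole-cohort" else "training-only"
  cols <- c("age", biomarker_names())
  imputed_cols <- character(); n_cells <- 0L
  means <- stats
  if (is.null(means)) {
    means <- vapply(cols, function(cl) mean(cohort[[cl]], na.rm = TRUE), numeric(1))
  }
  for (cl in cols) {
    miss <- is.na(cohort[[cl]])
    if (any(miss)) {
      if (is.na(means[[cl]])) stop("imputation error: no observed values in ", cl)
      cohort[[cl]][miss] <- means[[cl]]
      imputed_cols <- c(imputed_cols, cl)
      n_cells <- n_cells + sum(miss)
    }
  }
  attr(cohort, "imputed") <- TRUE
  report <- new_preprocess_report("impute_mean", fit_scope,
                                  imputed_cells = n_cells,
                                  imputed_columns = imputed_cols)
  report$fit_stats <- means
  list(cohort = cohort, report = report)
}

#' Encode sex as a 0/1 numeric feature
#'
#' Adds a `sex_code` column under the fixed mapping female = 0, male = 1. The
#' categorical `sex` column is retained: all stratified evaluation uses it, so
#' the (arbitrary, documented) encoding direction cannot affect per-sex
#' results.
#'
#' @param cohort a cohort.
#' @return The cohort with `sex_code` added and the encoding recorded.
#' @export
encode_sex <- function(cohort) {
  validate_cohort(cohort)
  cohort$sex_code <- as.numeric(cohort$sex == "male")
  attr(cohort, "sex_encoding") <- c(female = 0, male = 1)
  cohort
}

#' Recode the raw Selector to a 0/1 disease label
#'
#' The UCI distribution codes liver patients as Selector 1 and non-patients as
#' Selector 2. After recoding, `disease = 1` marks diseased patients.
#'
#' @param cohort a cohort with raw Selector values.
#' @return The cohort with `disease` in \{0, 1\} and the recoded flag set.
#' @export
recode_target <- function(cohort) {
  validate_cohort(cohort)
  if (is_recoded(cohort)) return(cohort)
  if (!all(cohort$disease %in% c(1, 2))) {
    bad <- which(!cohort$disease %in% c(1, 2))[1]
    stop(sprintf("validation error: Selector value %s at row %d outside {1, 2}",
                 cohort$disease[bad], bad))
  }
  cohort$disease <- as.integer(cohort$disease == 1)
  attr(cohort, "recoded") <- TRUE
  cohort
}

#' Min-max normalise age and the biomarkers
#'
#' Maps each feature x to (x - min) / (max - min), with min/max fit either on
#' this cohort or taken from statistics fit elsewhere (safe mode). The encoded
#' sex (already 0/1) and the target are not rescaled. A zero-range (constant)
#' feature maps to 0 rather than erroring, so degenerate synthetic cohorts pass
#' through the pipeline.
#'
#' @param cohort an imputed cohort (no missing cells).
#' @param stats optional scale parameters: a matrix with rownames = feature
#'   names and columns `min`, `max` (from a previous report's `scale_params`).
#' @return list with `cohort` (scaled flag set) and `report` (carries
#'   `scale_params`).
#' @export
minmax_scale <- function(cohort, stats = NULL) {
  validate_cohort(cohort)
  if (anyNA(cohort$ag_ratio)) stop("scale after imputation: ag_ratio has missing values")
  fit_scope <- if (is.null(stats)) "whole-cohort" else "training-only"
  cols <- SCALED_COLUMNS()
  if (is.null(stats)) {
    stats <- t(vapply(cols, function(cl) {
      c(min = min(cohort[[cl]]), max = max(cohort[[cl]]))
    }, numeric(2)))
  }
  for (cl in cols) {
    rng <- stats[cl, "max"] - stats[cl, "min"]
    cohort[[cl]] <- if (rng > 0) (cohort[[cl]] - stats[cl, "min"]) / rng else
      rep(0, nrow(cohort))
  }
  attr(cohort, "scaled") <- TRUE
  report <- new_preprocess_report("minmax_scale", fit_scope, scale_params = stats)
  list(cohort = cohort, report = report)
}

#' Run the full preparation pipeline
#'
#' Convenience wrapper: recode the target, encode sex, mean-impute and min-max
#' scale, with statistics fit on the whole cohort (the faithful scope).
#'
#' @param cohort a raw cohort as returned by [read_ilpd_csv()] or
#'   [generate_cohort()].
#' @return list with `cohort` (fully prepared) and `reports` (list of
#'   `preprocess_report`s).
#' @export
preprocess_cohort <- function(cohort) {
  cohort <- recode_target(cohort)
  cohort <- encode_sex(cohort)
  imp <- impute_mean(cohort)
  sc <- minmax_scale(imp$cohort)
  list(cohort = sc$cohort, reports = list(impute = imp$report, scale = sc$report))
}
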