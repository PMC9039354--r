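#' @useDynLib liverfair, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor quantile rnorm runif rbinom rlnorm sd pt var predict
#' @importFrom utils read.csv write.csv
NULL

# Codebook column order of the UCI ILPD distribution. Tie-breaks in feature
# rankings use this order, so it is defined once here.
ILPD_COLUMNS <- c(
  "age", "sex", "total_bilirubin", "direct_bilirubin", "alkaline_phosphatase",
  "alanine_aminotransferase", "aspartate_aminotransferase", "total_proteins",
  "albumin", "ag_ratio", "disease"
)

#' Biomarker, feature and sex-level constants
#'
#' `biomarker_names()` returns the eight serum liver-function columns;
#' `feature_names()` returns the model feature set in codebook order
#' (age, encoded sex, then the biomarkers).
#' @return Character vector of column names.
#' @export
biomarker_names <- function() {
  c("total_bilirubin", "direct_bilirubin", "alkaline_phosphatase",
    "alanine_aminotransferase", "aspartate_aminotransferase",
    "total_proteins", "albumin", "ag_ratio")
}

#' @rdname biomarker_names
#' @export
feature_names <- function() c("age", "sex_code", biomarker_names())

SEX_LEVELS <- c("female", "male")
PROVENANCE_LEVELS <- c("original", "smote", "generator")

#' Construct a cohort
#'
#' A cohort is the unit passed between pipeline stages: a data frame of patient
#' records (one row per patient) carrying preprocessing-state flags as
#' attributes. Columns: `age`, `sex` (factor female/male), the eight biomarkers
#' (see [biomarker_names()]), `disease`, `provenance`, and `sex_code` once
#' [encode_sex()] has run.
#'
#' @param records data frame with at least `age`, `sex`, the biomarkers,
#'   `disease`; `provenance` defaults to `"original"`.
#' @param name label for the cohort (e.g. `"dataset1"`).
#' @param recoded has `disease` been recoded to 0/1 (1 = liver patient)? If
#'   `FALSE`, `disease` still carries raw UCI Selector codes (1/2).
#' @param imputed,scaled preprocessing-state flags.
#' @param validate run invariant checks.
#' @return An object of class `cohort` (a data frame).
#' @export
new_cohort <- function(records, name = "cohort", recoded = FALSE,
                       imputed = FALSE, scaled = FALSE, validate = TRUE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!is.factor(records$sex)) {
    records$sex <- factor(as.character(records$sex), levels = SEX_LEVELS)
  }
  if (is.null(records$provenance)) records$provenance <- "original"
  if (!is.factor(records$provenance)) {
    records$provenance <- factor(as.character(records$provenance),
                                 levels = PROVENANCE_LEVELS)
  }
  rownames(records) <- NULL
  structure(records,
            class = c("cohort", "data.frame"),
            cohort_name = name,
            recoded = recoded, imputed = imputed, scaled = scaled,
            sex_encoding = attr(records, "sex_encoding", exact = TRUE)) -> x
  if (validate) validate_cohort(x)
  x
}

#' @rdname new_cohort
#' @param x a cohort.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  required <- c("age", "sex", biomarker_names(), "disease", "provenance")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(x$sex)) stop("sex must be defined for every record")
  for (col in setdiff(c("age", biomarker_names()), "ag_ratio")) {
    if (anyNA(x[[col]])) {
      stop("only ag_ratio is permitted to be missing; found NA in ", col)
    }
  }
  if (!attr(x, "scaled")) {
    for (col in biomarker_names()) {
      v <- x[[col]]
      if (any(v[!is.na(v)] < 0)) stop("negative biomarker value in ", col)
    }
  }
  if (attr(x, "imputed") && anyNA(x$ag_ratio)) {
    stop("imputed flag set but ag_ratio still has missing values")
  }
  if (attr(x, "recoded") && !all(x$disease %in% c(0, 1))) {
    stop("recoded flag set but disease has values outside {0, 1}")
  }
  invisible(x)
}

#' @export
`[.cohort` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("sex", "disease") %in% names(out))) {
    for (a in c("cohort_name", "recoded", "imputed", "scaled", "sex_encoding")) {
      attr(out, a) <- attr(x, a, exact = TRUE)
    }
    class(out) <- c("cohort", "data.frame")
    rownames(out) <- NULL
  }
  out
}

# Row-subset a cohort, preserving state flags.
cohort_rows <- function(x, idx) x[idx, , drop = FALSE]

# Stack cohorts with identical columns, preserving the first one's flags.
cohort_rbind <- function(x, y, name = attr(x, "cohort_name")) {
  y <- as.data.frame(y)[, names(x), drop = FALSE]
  out <- rbind(as.data.frame(x), y)
  new_cohort(out, name = name,
             recoded = attr(x, "recoded"), imputed = attr(x, "imputed"),
             scaled = attr(x, "scaled"), validate = FALSE) -> z
  attr(z, "sex_encoding") <- attr(x, "sex_encoding", exact = TRUE)
  z
}

is_recoded <- function(x) isTRUE(attr(x, "recoded"))

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort '%s': %d records%s%s%s>\n",
              attr(x, "cohort_name"), nrow(x),
              if (is_recoded(x)) ", recoded" else ", raw selector",
              if (isTRUE(attr(x, "imputed"))) ", imputed" else "",
              if (isTRUE(attr(x, "scaled"))) ", scaled" else ""))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Summarise cohort composition
#'
#' Tabulates record counts by sex and disease class, with per-sex totals,
#' per-class totals and the grand total. Requires the target to have been
#' recoded to 0/1 (see [recode_target()]).
#'
#' @param cohort a recoded cohort.
#' @return A `cohort_summary`: list with `counts` (2x2 sex-by-class matrix),
#'   `sex_totals`, `class_totals`, `total`.
#' @export
summarize_cohort <- function(cohort) {
  validate_cohort(cohort)
  if (!is_recoded(cohort)) {
    stop("disease has not been recoded to 0/1; run recode_target() first")
  }
  counts <- table(factor(cohort$sex, levels = SEX_LEVELS),
                  factor(cohort$disease, levels = c(0, 1)))
  counts <- matrix(as.integer(counts), nrow = 2,
                   dimnames = list(sex = SEX_LEVELS, disease = c("0", "1")))
  structure(list(counts = counts,
                 sex_totals = rowSums(counts),
                 class_totals = colSums(counts),
                 total = sum(counts)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort composition (sex x disease):\n")
  print(cbind(x$counts, total = x$sex_totals))
  cat(sprintf("class totals: healthy %d, diseased %d; grand total %d\n",
              x$class_totals[["0"]], x$class_totals[["1"]], x$total))
  invisible(x)
}
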