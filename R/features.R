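# Sex-stratified feature exploration and recursive feature elimination.
#
# Pearson ranking orders features by |r| with the disease label within a sex
# stratum; the IQR profile summarises how much spread (hence potential
# discriminative range) each normalised biomarker has per sex. RFE wraps a
# learner: drop the least important feature, refit, repeat until n_keep remain.

scope_rows <- function(cohort, scope) {
  scope <- match.arg(scope, c("all", "female", "male"))
  if (scope == "all") cohort else cohort_rows(cohort, cohort$sex == scope)
}

new_feature_ranking <- function(scope, method, entries) {
  structure(list(scope = scope, method = method, entries = entries),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking: %s, scope %s>\n", x$method, x$scope))
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Rank features by Pearson correlation with the disease label
#'
#' Computes, within the given sex stratum, the Pearson correlation of each
#' model feature with the 0/1 disease label, and ranks by absolute value
#' (descending). A zero-variance feature in scope (e.g. the sex code inside a
#' single-sex stratum) gets correlation 0 with a warning. Ties are broken by
#' codebook column order for determinism.
#'
#' @param cohort a preprocessed cohort (encoded, no missing cells).
#' @param scope `"all"`, `"female"` or `"male"`.
#' @param features feature columns to rank (default: all model features).
#' @return A `feature_ranking` with `entries` columns feature/score/rank.
#' @export
pearson_rank <- function(cohort, scope = "all", features = NULL) {
  if (is.null(features)) features <- intersect(feature_names(), names(cohort))
  sub <- scope_rows(cohort, scope)
  if (nrow(sub) < 3) stop("need at least 3 records in scope")
  y <- sub$disease
  if (length(unique(y)) < 2) stop("both classes must be present in scope")
  r <- vapply(features, function(f) {
    v <- sub[[f]]
    if (stats::sd(v) == 0) {
      warning("zero-variance feature in scope: ", f, call. = FALSE)
      return(0)
    }
    stats::cor(v, y)
  }, numeric(1))
  ord <- order(-abs(r), match(features, feature_names()))
  entries <- data.frame(feature = features[ord], score = unname(r[ord]),
                        rank = seq_along(features), stringsAsFactors = FALSE)
  new_feature_ranking(scope, "pearson", entries)
}

#' Per-sex interquartile-range profile of the normalised biomarkers
#'
#' On the min-max-normalised scale, computes each biomarker's IQR (Q3 - Q1,
#' linear-interpolation quantiles, `type = 7`) within the given sex stratum,
#' and their arithmetic mean. A smaller mean IQR indicates that the biomarkers
#' span less of their observed range for that stratum — less room for a
#' classifier to separate the classes.
#'
#' @param cohort a scaled cohort.
#' @param scope `"all"`, `"female"` or `"male"`.
#' @return An `iqr_profile`: list with `scope`, `per_feature_iqr` (named
#'   vector over [biomarker_names()]) and `mean_iqr`.
#' @export
iqr_profile <- function(cohort, scope = "all") {
  if (!isTRUE(attr(cohort, "scaled"))) stop("iqr_profile expects a scaled cohort")
  sub <- scope_rows(cohort, scope)
  if (!nrow(sub)) stop("empty scope")
  iqrs <- vapply(biomarker_names(), function(b) {
    q <- stats::quantile(sub[[b]], c(0.25, 0.75), type = 7, names = FALSE)
    q[2] - q[1]
  }, numeric(1))
  structure(list(scope = scope, per_feature_iqr = iqrs, mean_iqr = mean(iqrs)),
            class = "iqr_profile")
}

#' @export
print.iqr_profile <- function(x, ...) {
  cat(sprintf("<iqr_profile: scope %s, mean IQR %.4f>\n", x$scope, x$mean_iqr))
  print(round(x$per_feature_iqr, 4))
  invisible(x)
}

#' Recursive feature elimination to a top-n subset
#'
#' Iteratively fits the learner on the remaining features, drops the single
#' feature with the lowest importance, and repeats until `n_keep` remain
#' (step = 1). Importance comes from the learner where it exposes one
#' (coefficient magnitude for logistic regression, impurity importance for the
#' forest); for learners exposing neither (Gaussian naive Bayes, RBF-kernel
#' SVM) a ridge-logistic surrogate performs the elimination and the surrogate
#' is recorded on the result. Survivor ranks reverse the elimination order:
#' the feature that would have been eliminated last is rank 1.
#'
#' @param cohort a preprocessed (training) cohort.
#' @param learner learner family: `"random_forest"`, `"logistic_regression"`,
#'   `"svm"` or `"gaussian_nb"`.
#' @param n_keep number of surviving features (default 5).
#' @param features candidate features (default: all model features present).
#' @param seed RNG seed (forest fits are stochastic).
#' @return A `feature_ranking` (method `"rfe"`) whose `entries` hold the
#'   `n_keep` survivors; attribute `eliminated` lists dropped features in
#'   elimination order, attribute `surrogate` names the importance source.
#' @export
rfe_top_features <- function(cohort, learner = "logistic_regression",
                             n_keep = 5, features = NULL, seed = NULL) {
  learner <- match.arg(learner, LEARNER_FAMILIES)
  if (is.null(features)) features <- intersect(feature_names(), names(cohort))
  if (n_keep >= length(features)) {
    entries <- data.frame(feature = features, score = NA_real_,
                          rank = seq_along(features), stringsAsFactors = FALSE)
    return(new_feature_ranking("all", "rfe", entries))
  }
  surrogate <- if (learner %in% c("svm", "gaussian_nb")) "logistic_regression" else learner
  if (!is.null(seed)) set.seed(seed)
  remaining <- features
  eliminated <- character()
  y <- cohort$disease
  while (length(remaining) > n_keep) {
    imp <- learner_importance(cohort, remaining, surrogate)
    # lowest importance goes; ties broken by codebook order (later column drops)
    ord <- order(imp, -match(remaining, feature_names()))
    drop_f <- remaining[ord[1]]
    eliminated <- c(eliminated, drop_f)
    remaining <- setdiff(remaining, drop_f)
  }
  final_imp <- learner_importance(cohort, remaining, surrogate)
  ord <- order(-final_imp, match(remaining, feature_names()))
  entries <- data.frame(feature = remaining[ord], score = unname(final_imp[ord]),
                        rank = seq_along(remaining), stringsAsFactors = FALSE)
  out <- new_feature_ranking("all", "rfe", entries)
  attr(out, "eliminated") <- eliminated
  attr(out, "surrogate") <- surrogate
  out
}

# Per-feature importance used inside RFE.
learner_importance <- function(cohort, features, family) {
  x <- as.matrix(as.data.frame(cohort)[, features, drop = FALSE])
  y <- cohort$disease
  if (family == "random_forest") {
    fit <- fit_learner(cohort, family = "random_forest", features = features)
    imp <- fit$importance
  } else {
    fit <- fit_learner(cohort, family = "logistic_regression", features = features)
    imp <- abs(fit$coefficients)
  }
  stats::setNames(as.numeric(imp), features)
}
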