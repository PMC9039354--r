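# Seeded generator for ILPD-like cohorts. Liver-function biomarkers are
# right-skewed and non-negative, so each is drawn log-normal; disease shifts
# the log-mean by a per-feature effect, and for diseased females that shift is
# multiplied by an attenuation factor gamma in [0, 1] — the "milder female
# expression of liver injury" mechanism the audit is meant to detect.
# gamma = 1 with equal sex counts and prevalences is the exchangeable-sexes
# null used for calibration.

# Per-biomarker baseline (log-mean, log-sd) and diseased log-scale shift.
# Chosen once to resemble liver-panel magnitudes (bilirubins in mg/dL, enzymes
# in IU/L, proteins/albumin in g/dL); not fit to the real ILPD.
DEFAULT_BASELINE <- data.frame(
  feature = biomarker_names(),
  log_mean = c(log(0.9), log(0.25), log(190), log(28), log(32),
               log(6.5), log(3.3), log(1.0)),
  log_sd = c(0.45, 0.55, 0.30, 0.55, 0.55, 0.10, 0.18, 0.22),
  effect = c(0.28, 0.36, 0.18, 0.34, 0.36, -0.025, -0.10, -0.13),
  stringsAsFactors = FALSE
)

#' Parameterise the synthetic cohort distribution
#'
#' @param n_female,n_male sex counts.
#' @param prevalence_female,prevalence_male per-sex disease probabilities.
#' @param baseline data frame with columns feature/log_mean/log_sd/effect for
#'   the eight biomarkers (default: packaged liver-panel-like constants).
#' @param female_attenuation gamma in [0, 1]: multiplier on every biomarker
#'   effect for diseased females. 1 = no sex difference in disease expression
#'   (the null); smaller values weaken the female disease signal.
#' @param age_mean,age_sd age distribution (years; truncated to [4, 90] and
#'   rounded).
#' @param missing_rate proportion of A/G-ratio cells blanked at random.
#' @param seed RNG seed.
#' @return A `generator_spec`.
#' @export
generator_spec <- function(n_female, n_male, prevalence_female, prevalence_male,
                           baseline = DEFAULT_BASELINE, female_attenuation = 1,
                           age_mean = 44, age_sd = 16, missing_rate = 0,
                           seed = 1) {
  stopifnot(n_female > 0, n_male > 0,
            prevalence_female > 0, prevalence_female < 1,
            prevalence_male > 0, prevalence_male < 1,
            female_attenuation >= 0, female_attenuation <= 1,
            missing_rate >= 0, missing_rate < 1,
            identical(sort(baseline$feature), sort(biomarker_names())))
  structure(list(n_female = n_female, n_male = n_male,
                 prevalence_female = prevalence_female,
                 prevalence_male = prevalence_male,
                 baseline = baseline, female_attenuation = female_attenuation,
                 age_mean = age_mean, age_sd = age_sd,
                 missing_rate = missing_rate, seed = seed),
            class = "generator_spec")
}

#' The packaged ILPD-like default spec
#'
#' Sizes and prevalences mirror the real cohort's composition (142 females of
#' whom 92 diseased, 441 males of whom 324 diseased), with a handful of
#' missing A/G ratios and moderate female attenuation (gamma = 0.7).
#'
#' @param ... overrides passed to [generator_spec()].
#' @return A `generator_spec`.
#' @export
ilpd_like_spec <- function(...) {
  args <- utils::modifyList(
    list(n_female = 142, n_male = 441,
         prevalence_female = 92 / 142, prevalence_male = 324 / 441,
         female_attenuation = 0.7, missing_rate = 4 / 583, seed = 1),
    list(...))
  do.call(generator_spec, args)
}

#' The exchangeable-sexes null spec
#'
#' gamma = 1, equal sex counts, equal prevalences: relabelling the sexes
#' leaves the data distribution invariant, so any audit disparity on cohorts
#' from this spec is pure noise — the calibration regime.
#'
#' @param n per-sex count (default 200).
#' @param prevalence shared disease probability (default 0.5).
#' @param ... overrides passed to [generator_spec()].
#' @return A `generator_spec`.
#' @export
null_spec <- function(n = 200, prevalence = 0.5, ...) {
  args <- utils::modifyList(
    list(n_female = n, n_male = n,
         prevalence_female = prevalence, prevalence_male = prevalence,
         female_attenuation = 1, missing_rate = 0, seed = 1),
    list(...))
  do.call(generator_spec, args)
}

#' Generate a synthetic cohort
#'
#' Draws records independently: sex by the fixed counts, disease ~
#' Bernoulli(prevalence of that sex), each biomarker log-normal with log-mean
#' `baseline + effect * disease * (gamma if female)`, age truncated-normal
#' rounded to whole years. A/G-ratio cells are blanked at `missing_rate`.
#' Deterministic given the spec's seed.
#'
#' @param spec a [generator_spec()].
#' @param seed optional override of `spec$seed`.
#' @return list with `cohort` (recoded 0/1 target, provenance `"generator"`)
#'   and `truth` (the spec, realised sex-by-class counts, realised log-scale
#'   effect per feature and sex).
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(if (is.null(seed)) spec$seed else seed)
  n <- spec$n_female + spec$n_male
  sex <- factor(rep(SEX_LEVELS, c(spec$n_female, spec$n_male)), levels = SEX_LEVELS)
  prev <- ifelse(sex == "female", spec$prevalence_female, spec$prevalence_male)
  disease <- rbinom(n, 1, prev)

  age <- round(pmin(pmax(rnorm(n, spec$age_mean, spec$age_sd), 4), 90))
  records <- data.frame(age = age, sex = sex, stringsAsFactors = FALSE)
  gamma <- ifelse(sex == "female", spec$female_attenuation, 1)
  for (i in seq_len(nrow(spec$baseline))) {
    b <- spec$baseline[i, ]
    mu <- b$log_mean + b$effect * disease * gamma
    records[[b$feature]] <- rlnorm(n, meanlog = mu, sdlog = b$log_sd)
  }
  if (spec$missing_rate > 0) {
    blank <- runif(n) < spec$missing_rate
    records$ag_ratio[blank] <- NA_real_
  }
  records$disease <- disease
  records$provenance <- "generator"

  cohort <- new_cohort(records, name = "synthetic", recoded = TRUE)
  counts <- table(sex = sex, disease = factor(disease, levels = c(0, 1)))
  effects <- outer(c(female = spec$female_attenuation, male = 1),
                   stats::setNames(spec$baseline$effect, spec$baseline$feature))
  list(cohort = cohort,
       truth = list(spec = spec, counts = counts, realized_effects = effects))
}
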