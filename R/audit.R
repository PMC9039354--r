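# The evaluation core: per-sex confusion matrices, the standard proportion
# metrics, rank-based ROC AUC, the male-minus-female disparity statistic, and
# paired t-tests over repeated train/test runs.
#
# Metric conventions: everything is stored as a proportion in [0, 1] and
# reported x100; a ratio with a zero denominator is NA ("undefined"), never
# zero-substituted, and undefined entries are dropped pairwise from disparity
# series with the drop count reported.

AUDIT_METRICS <- c("accuracy", "f_score", "roc_auc", "precision", "recall",
                   "fnr", "tnr", "fpr", "tpr")

#' Tally a confusion matrix from 0/1 labels
#'
#' @param truth,predicted equal-length 0/1 vectors.
#' @return A `confusion_counts`: list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_from_predictions <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("length mismatch")
  stopifnot(all(truth %in% c(0, 1)), all(predicted %in% c(0, 1)))
  structure(list(
    tp = sum(truth == 1 & predicted == 1),
    tn = sum(truth == 0 & predicted == 0),
    fp = sum(truth == 0 & predicted == 1),
    fn = sum(truth == 1 & predicted == 0)
  ), class = "confusion_counts")
}

add_confusions <- function(a, b) {
  structure(list(tp = a$tp + b$tp, tn = a$tn + b$tn,
                 fp = a$fp + b$fp, fn = a$fn + b$fn),
            class = "confusion_counts")
}

#' Derive the proportion metrics from a confusion matrix
#'
#' Accuracy = (TP+TN)/n; precision = TP/(TP+FP); recall = TPR = TP/(TP+FN);
#' F = 2PR/(P+R); TNR = TN/(TN+FP); FNR = 1 - recall; FPR = 1 - TNR. Ratios
#' with zero denominators are `NA`.
#'
#' @param cc a `confusion_counts`.
#' @return Named numeric vector over the threshold metrics (no AUC here).
#' @export
metrics_from_confusion <- function(cc) {
  n <- cc$tp + cc$tn + cc$fp + cc$fn
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  accuracy <- ratio(cc$tp + cc$tn, n)
  precision <- ratio(cc$tp, cc$tp + cc$fp)
  recall <- ratio(cc$tp, cc$tp + cc$fn)
  f_score <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  tnr <- ratio(cc$tn, cc$tn + cc$fp)
  c(accuracy = accuracy, f_score = f_score, precision = precision,
    recall = recall, fnr = 1 - recall, tnr = tnr, fpr = 1 - tnr, tpr = recall)
}

#' Rank-based ROC AUC (Mann-Whitney with midrank ties)
#'
#' AUC = P(score of a random positive > score of a random negative) + half the
#' probability of a tie, computed from midranks.
#'
#' @param truth 0/1 labels.
#' @param scores continuous scores, larger = more disease-like.
#' @return AUC in [0, 1]; `NA` if only one class is present.
#' @export
rank_auc <- function(truth, scores) {
  stopifnot(length(truth) == length(scores))
  n_pos <- sum(truth == 1); n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate a model on a test cohort, stratified by sex
#'
#' Predicts once on the full test set and partitions the same predictions by
#' the categorical sex field into all/female/male groups, computing the
#' confusion metrics and rank AUC per group. The all-group confusion is, by
#' construction, the element-wise sum of the sex confusions. A sex subgroup
#' containing a single class leaves that subgroup's class-conditional metrics
#' undefined and flags the run.
#'
#' @param model a `liverfair_model`.
#' @param test a test cohort containing both sexes.
#' @return list with `metrics` (data frame group/metric/value), `confusions`
#'   (per group) and `flagged`.
#' @export
stratified_evaluate <- function(model, test) {
  if (!all(SEX_LEVELS %in% test$sex)) stop("test cohort must contain both sexes")
  pred <- predict(model, test, type = "class")
  score <- predict(model, test, type = "score")
  truth <- as.data.frame(test)$disease
  groups <- list(all = rep(TRUE, nrow(test)),
                 female = test$sex == "female",
                 male = test$sex == "male")
  flagged <- FALSE
  confusions <- list(); rows <- list()
  for (g in names(groups)) {
    sel <- groups[[g]]
    cc <- confusion_from_predictions(truth[sel], pred[sel])
    confusions[[g]] <- cc
    m <- metrics_from_confusion(cc)
    auc <- rank_auc(truth[sel], score[sel])
    if (g != "all" && length(unique(truth[sel])) < 2) flagged <- TRUE
    m <- c(m, roc_auc = auc)
    rows[[g]] <- data.frame(group = g, metric = names(m), value = unname(m),
                            stringsAsFactors = FALSE)
  }
  list(metrics = do.call(rbind, rows)[, c("group", "metric", "value")],
       confusions = confusions, flagged = flagged)
}

#' Paired t-test on per-run male/female metric series
#'
#' t = mean(d) / (sd(d) / sqrt(n)) on the paired differences d = male -
#' female, two-sided p from the t distribution with n - 1 degrees of freedom.
#' A zero-variance nonzero difference reports the limit p = 0 with a
#' degenerate-variance flag; a zero-variance zero difference is t = 0, p = 1.
#'
#' @param male_series,female_series equal-length paired numeric vectors
#'   (proportions or percentages; `NA`s dropped pairwise).
#' @return list with `t_statistic`, `p_value`, `n`, `degenerate`.
#' @export
paired_ttest <- function(male_series, female_series) {
  stopifnot(length(male_series) == length(female_series))
  ok <- !is.na(male_series) & !is.na(female_series)
  d <- male_series[ok] - female_series[ok]
  n <- length(d)
  if (n < 2) return(list(t_statistic = NA_real_, p_value = NA_real_, n = n,
                         degenerate = FALSE))
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(t_statistic = 0, p_value = 1, n = n, degenerate = FALSE))
    return(list(t_statistic = sign(mean(d)) * Inf, p_value = 0, n = n, degenerate = TRUE))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  list(t_statistic = t_stat, p_value = 2 * stats::pt(-abs(t_stat), n - 1),
       n = n, degenerate = FALSE)
}

#' Male-minus-female disparity for one metric over a run series
#'
#' Disparity = mean(male) - mean(female) in percentage points, with the paired
#' t-test of the per-run differences. Negative values mean the female mean is
#' larger (a female advantage on benefit metrics, a female burden on error
#' metrics such as the false-negative rate).
#'
#' @param male_series,female_series per-run metric values as proportions,
#'   paired by run.
#' @param metric metric name for the row.
#' @return A one-row data frame: metric, male_mean, female_mean (percent),
#'   disparity (percentage points), t_statistic, p_value, n_runs, dropped.
#' @export
disparity <- function(male_series, female_series, metric = "metric") {
  stopifnot(length(male_series) == length(female_series))
  ok <- !is.na(male_series) & !is.na(female_series)
  m <- 100 * male_series[ok]; f <- 100 * female_series[ok]
  tt <- paired_ttest(m, f)
  data.frame(metric = metric,
             male_mean = mean(m), female_mean = mean(f),
             male_sd = stats::sd(m), female_sd = stats::sd(f),
             disparity = mean(m) - mean(f),
             t_statistic = tt$t_statistic, p_value = tt$p_value,
             n_runs = sum(ok), dropped = sum(!ok),
             stringsAsFactors = FALSE)
}

#' Configure an audit experiment
#'
#' The four experiment designs cross two factors: sex balancing of the
#' modelling data (experiments 2 and 4) and recursive feature elimination to a
#' top-5 subset (experiments 3 and 4). All experiments model the
#' class-balanced data (the minority healthy class is SMOTE-oversampled to
#' parity first).
#'
#' @param experiment 1-4.
#' @param learner learner family.
#' @param n_runs repeated build/train/test cycles (default 100).
#' @param test_fraction held-out share (default 0.30).
#' @param seed base seed; run r uses seed + r.
#' @param mode `"faithful"` reproduces the oversample-and-prepare-before-split
#'   pipeline (statistics fit on the whole cohort, synthetic records may land
#'   in test); `"safe"` is the leakage-free variant: split first, fit
#'   imputation/scaling on the training fold, oversample the training fold
#'   only, evaluate on original records.
#' @param smote_k SMOTE neighbourhood size.
#' @param rfe_n_keep features kept by RFE (default 5).
#' @param tune grid-search hyperparameters per run.
#' @param grids optional per-family tuning grids.
#' @param max_retries split redraw bound.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(experiment, learner, n_runs = 100,
                              test_fraction = 0.30, seed = 1,
                              mode = c("faithful", "safe"), smote_k = 5,
                              rfe_n_keep = 5, tune = TRUE, grids = NULL,
                              max_retries = 20) {
  stopifnot(experiment %in% 1:4)
  learner <- match.arg(learner, LEARNER_FAMILIES)
  mode <- match.arg(mode)
  structure(list(experiment = experiment, learner = learner, n_runs = n_runs,
                 test_fraction = test_fraction, seed = seed, mode = mode,
                 smote_k = smote_k, rfe_n_keep = rfe_n_keep, tune = tune,
                 grids = grids, max_retries = max_retries,
                 sex_balanced = experiment %in% c(2, 4),
                 rfe = experiment %in% c(3, 4)),
            class = "experiment_config")
}

# Independent component seeds derived from one run seed, all < 2^31.
derive_seeds <- function(run_seed) {
  set.seed(run_seed)
  stats::setNames(sample.int(.Machine$integer.max - 1, 4),
                  c("balance", "split", "learner", "rfe"))
}

audit_one_run <- function(cohort_raw, cohort_prepared, config, run_seed) {
  seeds <- derive_seeds(run_seed)
  if (config$mode == "faithful") {
    dat <- balance_classes(cohort_prepared, k_neighbors = config$smote_k,
                           seed = seeds[["balance"]])
    if (config$sex_balanced) {
      dat <- balance_sexes(dat, k_neighbors = config$smote_k,
                           seed = seeds[["balance"]] + 1L)
    }
    split <- train_test_split(dat, test_fraction = config$test_fraction,
                              seed = seeds[["split"]],
                              max_retries = config$max_retries)
  } else {
    split0 <- train_test_split(cohort_raw, test_fraction = config$test_fraction,
                               sex_balanced_training = config$sex_balanced,
                               seed = seeds[["split"]],
                               max_retries = config$max_retries)
    imp <- impute_mean(split0$train)
    sc <- minmax_scale(imp$cohort)
    train <- sc$cohort
    test <- minmax_scale(impute_mean(split0$test, stats = imp$report$fit_stats)$cohort,
                         stats = sc$report$scale_params)$cohort
    train <- balance_classes(train, k_neighbors = config$smote_k,
                             seed = seeds[["balance"]])
    split <- list(train = train, test = test)
  }

  features <- intersect(feature_names(), names(split$train))
  selected <- features
  if (config$rfe) {
    rk <- rfe_top_features(split$train, learner = config$learner,
                           n_keep = config$rfe_n_keep, features = features,
                           seed = seeds[["rfe"]])
    selected <- rk$entries$feature
  }
  model <- fit_learner(split$train, family = config$learner,
                       features = selected, tune = config$tune,
                       grid = config$grids[[config$learner]],
                       seed = seeds[["learner"]])
  ev <- stratified_evaluate(model, split$test)
  list(metrics = ev$metrics, confusions = ev$confusions, flagged = ev$flagged,
       selected = selected, seed = run_seed)
}

#' Run one audit experiment
#'
#' Executes `n_runs` independent build/train/test cycles (run r seeded with
#' `seed + r`; balancing, splitting, RFE and learner fits draw from
#' independent streams derived from the run seed), evaluates each stratified
#' by sex, and summarises the male/female means, male-minus-female disparities
#' and paired-t significance for the nine report metrics.
#'
#' @param cohort a raw cohort (recoded target not required; recoding/encoding
#'   are applied here, and in faithful mode imputation and scaling are fit on
#'   the whole cohort before the run loop).
#' @param config an [experiment_config()].
#' @return An `audit_result`: list with `runs` (long per-run data frame:
#'   run, seed, group, metric, value), `disparities` (one row per metric),
#'   `selected_features` (per run), `flagged_runs`, `config`.
#' @export
run_experiment <- function(cohort, config) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- encode_sex(recode_target(cohort))
  prepared <- NULL
  if (config$mode == "faithful") {
    prepared <- minmax_scale(impute_mean(cohort)$cohort)$cohort
  }
  runs <- vector("list", config$n_runs)
  selected <- vector("list", config$n_runs)
  flagged <- logical(config$n_runs)
  for (r in seq_len(config$n_runs)) {
    one <- audit_one_run(cohort, prepared, config, run_seed = config$seed + r)
    m <- one$metrics
    m$run <- r; m$seed <- one$seed
    runs[[r]] <- m
    selected[[r]] <- one$selected
    flagged[r] <- one$flagged
  }
  if (mean(flagged) > 0.10) {
    stop(sprintf("experiment aborted: %d of %d runs degenerate (single-class sex subgroup)",
                 sum(flagged), config$n_runs))
  }
  runs <- do.call(rbind, runs)[, c("run", "seed", "group", "metric", "value")]

  disparities <- do.call(rbind, lapply(AUDIT_METRICS, function(met) {
    m <- runs$value[runs$group == "male" & runs$metric == met]
    f <- runs$value[runs$group == "female" & runs$metric == met]
    disparity(m[order(runs$run[runs$group == "male" & runs$metric == met])],
              f[order(runs$run[runs$group == "female" & runs$metric == met])],
              metric = met)
  }))
  structure(list(runs = runs, disparities = disparities,
                 selected_features = selected, flagged_runs = which(flagged),
                 config = config),
            class = "audit_result")
}

#' @export
print.audit_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<audit_result: experiment %d, %s, %d runs, mode %s>\n",
              cfg$experiment, cfg$learner, cfg$n_runs, cfg$mode))
  d <- x$disparities
  d[-1] <- lapply(d[-1], function(v) round(v, 3))
  print(d, row.names = FALSE)
  invisible(x)
}

#' Run the full experiment-by-learner grid
#'
#' Crosses the requested experiments (default 1-4) with the requested learner
#' families (default all four = 16 experiment runs) and returns one
#' `audit_result` per cell.
#'
#' @param cohort a raw cohort.
#' @param experiments subset of 1:4.
#' @param learners subset of the four families.
#' @param ... passed to [experiment_config()] (n_runs, seed, mode, tune, ...).
#' @return Named list of `audit_result`s (`"exp1_random_forest"`, ...), class
#'   `audit_grid`.
#' @export
run_grid <- function(cohort, experiments = 1:4, learners = LEARNER_FAMILIES, ...) {
  out <- list()
  for (e in experiments) {
    for (l in learners) {
      cfg <- experiment_config(experiment = e, learner = l, ...)
      out[[sprintf("exp%d_%s", e, l)]] <- run_experiment(cohort, cfg)
    }
  }
  structure(out, class = "audit_grid")
}

#' Write audit report tables
#'
#' One CSV per (experiment, learner) with the disparity rows (metric, male and
#' female means and SDs, disparity in percentage points, t, p), plus a
#' long-format master file of every per-run metric value.
#'
#' @param results an `audit_result` or `audit_grid`.
#' @param dir output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_report_tables <- function(results, dir) {
  if (inherits(results, "audit_result")) {
    results <- stats::setNames(
      list(results),
      sprintf("exp%d_%s", results$config$experiment, results$config$learner))
  }
  if (!length(results)) stop("no result tables to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  master <- list()
  for (nm in names(results)) {
    res <- results[[nm]]
    path <- file.path(dir, paste0("disparity_", nm, ".csv"))
    utils::write.csv(res$disparities, path, row.names = FALSE)
    files <- c(files, path)
    runs <- res$runs
    runs$table <- nm
    master[[nm]] <- runs
  }
  master_path <- file.path(dir, "per_run_metrics.csv")
  utils::write.csv(do.call(rbind, master), master_path, row.names = FALSE)
  invisible(c(files, master_path))
}
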