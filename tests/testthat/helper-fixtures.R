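# Fixture builders used across the suite. Everything is generated in code;
# nothing is read from disk except the tiny packaged example CSV.

# Cohort with exact sex-by-class cell counts and ILPD-like continuous features.
make_cell_cohort <- function(n_f0, n_f1, n_m0, n_m1, seed = 1, scaled = FALSE) {
  set.seed(seed)
  n <- n_f0 + n_f1 + n_m0 + n_m1
  sex <- rep(c("female", "female", "male", "male"), c(n_f0, n_f1, n_m0, n_m1))
  disease <- rep(c(0L, 1L, 0L, 1L), c(n_f0, n_f1, n_m0, n_m1))
  rec <- data.frame(age = round(runif(n, 20, 75)), sex = sex,
                    stringsAsFactors = FALSE)
  for (b in biomarker_names()) {
    rec[[b]] <- rlnorm(n, meanlog = log(2) + 0.4 * disease, sdlog = 0.5)
  }
  rec$disease <- disease
  x <- new_cohort(rec, name = "cells", recoded = TRUE)
  if (scaled) x <- minmax_scale(x)$cohort
  x
}

# Hand-written 3-row ILPD-dialect CSV (one blank A/G cell). Synthetic rows.
write_mini_ilpd <- function(path, header = FALSE) {
  lines <- c(
    "65,Female,0.7,0.1,187,16,18,6.8,3.3,0.9,1",
    "62,male,10.9,5.5,699,64,100,7.5,3.2,,1",
    "46, Male ,1.8,0.7,208,19,14,7.6,4.4,1.3,2")
  if (header) lines <- c("Age,Gender,TB,DB,Alkphos,Sgpt,Sgot,TP,ALB,AG,Selector", lines)
  writeLines(lines, path)
  path
}

# Linearly separable two-feature training cohort (both sexes, both classes).
make_separable_cohort <- function(n_per = 20, seed = 3) {
  set.seed(seed)
  cohort <- make_cell_cohort(n_per, n_per, n_per, n_per, seed = seed)
  cohort$total_bilirubin <- ifelse(cohort$disease == 1,
                                   runif(nrow(cohort), 3, 4),
                                   runif(nrow(cohort), 0, 1))
  cohort$albumin <- ifelse(cohort$disease == 1,
                           runif(nrow(cohort), 0, 1),
                           runif(nrow(cohort), 3, 4))
  encode_sex(cohort)
}

# Exhaustive positive-by-negative pair-counting AUC oracle.
auc_pair_oracle <- function(truth, scores) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Brute-force metric oracle straight from the prediction lists.
metric_oracle <- function(truth, pred) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1
    if (truth[i] == 0 && pred[i] == 0) tn <- tn + 1
    if (truth[i] == 0 && pred[i] == 1) fp <- fp + 1
    if (truth[i] == 1 && pred[i] == 0) fn <- fn + 1
  }
  safe <- function(a, b) if (b > 0) a / b else NA_real_
  prec <- safe(tp, tp + fp); rec <- safe(tp, tp + fn)
  f <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  tnr <- safe(tn, tn + fp)
  c(accuracy = safe(tp + tn, tp + tn + fp + fn), f_score = f,
    precision = prec, recall = rec, fnr = 1 - rec, tnr = tnr,
    fpr = 1 - tnr, tpr = rec)
}
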