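# SMOTE oversampling and the two balancing schemes used on the ILPD:
# class balancing (oversample the minority class to parity) and sex balancing
# (oversample the under-represented sex to parity), plus the 70/30 train/test
# split policies, including the sex-balanced-training variant.
#
# The SMOTE interpolation itself is written here rather than delegated: the
# synthetic-record mechanism (seed record, k-NN within group, convex
# interpolation, inherited labels) is the primitive the balancing schemes and
# their tests are about.

# Continuous columns used for neighbour search and interpolation. The
# categorical sex, its 0/1 code and the disease label are inherited from the
# seed record, never interpolated.
smote_feature_cols <- function(cohort) {
  intersect(c("age", biomarker_names()), names(cohort))
}

#' Generate SMOTE records within a homogeneous group
#'
#' Classic SMOTE interpolation: each synthetic record is `x + u * (x_nn - x)`
#' with `u ~ Uniform(0, 1)`, where `x` is a seed record drawn uniformly (with
#' replacement) from the group and `x_nn` is one of its `k` nearest neighbours
#' (Euclidean distance on the continuous features) within the same group. Sex,
#' its encoding and the disease label are inherited from the seed record;
#' provenance is set to `"smote"`.
#'
#' @param group a cohort subset homogeneous in the attribute being balanced
#'   (same class, or same sex); must be complete in the continuous features.
#' @param n_new number of synthetic records to produce (`target_count -
#'   nrow(group)` in the balancing schemes).
#' @param k_neighbors neighbourhood size (default 5, the conventional SMOTE
#'   default; must be `< nrow(group)`).
#' @param seed RNG seed; the draw is deterministic given it.
#' @return A data frame of `n_new` synthetic records with the group's columns.
#' @export
smote_generate <- function(group, n_new, k_neighbors = 5, seed = NULL) {
  if (nrow(group) <= k_neighbors) {
    stop(sprintf("parameter error: group size %d must exceed k_neighbors = %d",
                 nrow(group), k_neighbors))
  }
  if (n_new < 0) stop("parameter error: target_count below current group size")
  cols <- smote_feature_cols(group)
  feats <- as.matrix(as.data.frame(group)[, cols, drop = FALSE])
  if (anyNA(feats)) stop("SMOTE requires complete features; impute first")
  if (n_new == 0) return(as.data.frame(group)[0, , drop = FALSE])
  if (!is.null(seed)) set.seed(seed)

  nn <- FNN::get.knn(feats, k = k_neighbors)$nn.index
  seed_idx <- sample.int(nrow(group), n_new, replace = TRUE)
  nn_pick <- sample.int(k_neighbors, n_new, replace = TRUE)
  u <- runif(n_new)
  nbr_idx <- nn[cbind(seed_idx, nn_pick)]

  synth <- as.data.frame(group)[seed_idx, , drop = FALSE]
  synth[, cols] <- feats[seed_idx, , drop = FALSE] +
    u * (feats[nbr_idx, , drop = FALSE] - feats[seed_idx, , drop = FALSE])
  synth$provenance <- factor("smote", levels = PROVENANCE_LEVELS)
  attr(synth, "seed_index") <- seed_idx
  attr(synth, "neighbor_index") <- nbr_idx
  attr(synth, "u") <- u
  rownames(synth) <- NULL
  synth
}

#' Balance disease classes by oversampling the minority class
#'
#' Oversamples the minority disease class via [smote_generate()] until class
#' counts are exactly equal (Dataset 2 of the standard ILPD balancing: 167
#' healthy / 416 diseased becomes 416 / 416). Neighbour search is restricted to
#' the minority class but spans both sexes; each synthetic record inherits its
#' seed record's sex, which is what makes later sex-stratified evaluation of
#' the balanced data well defined. Original records are never modified.
#'
#' @param cohort a recoded cohort with both classes present.
#' @param k_neighbors,seed passed to [smote_generate()].
#' @return The cohort with synthetic minority records appended
#'   (`provenance = "smote"`).
#' @export
balance_classes <- function(cohort, k_neighbors = 5, seed = NULL) {
  validate_cohort(cohort)
  if (!is_recoded(cohort)) stop("recode the target before balancing")
  counts <- table(factor(cohort$disease, levels = c(0, 1)))
  if (any(counts == 0)) stop("both classes must be present")
  if (counts[["0"]] == counts[["1"]]) return(cohort)
  minority <- if (counts[["0"]] < counts[["1"]]) 0 else 1
  group <- cohort_rows(cohort, cohort$disease == minority)
  n_new <- abs(counts[["1"]] - counts[["0"]])
  synth <- smote_generate(group, n_new, k_neighbors = k_neighbors, seed = seed)
  cohort_rbind(cohort, synth, name = "dataset2")
}

#' Balance sexes by oversampling the under-represented sex
#'
#' Oversamples the rarer sex via [smote_generate()] until sex totals are
#' exactly equal (Dataset 3: applied after [balance_classes()], 237 female /
#' 595 male becomes 595 / 595). Neighbours are sought within that sex only, and
#' each synthetic record inherits its seed record's disease label, so the
#' synthetic females' class mix follows the geometry of the female subgroup.
#'
#' @param cohort a recoded cohort.
#' @param k_neighbors,seed passed to [smote_generate()].
#' @param within_class if `TRUE`, balance the rarer sex class-by-class
#'   (neighbour search within sex x class cells) instead of across the whole
#'   sex group.
#' @return The cohort with synthetic records appended.
#' @export
balance_sexes <- function(cohort, k_neighbors = 5, seed = NULL,
                          within_class = FALSE) {
  validate_cohort(cohort)
  if (!is_recoded(cohort)) stop("recode the target before balancing")
  counts <- table(factor(cohort$sex, levels = SEX_LEVELS))
  if (counts[["female"]] == counts[["male"]]) return(cohort)
  rare <- if (counts[["female"]] < counts[["male"]]) "female" else "male"
  n_new_total <- abs(counts[["male"]] - counts[["female"]])
  if (!within_class) {
    group <- cohort_rows(cohort, cohort$sex == rare)
    synth <- smote_generate(group, n_new_total, k_neighbors = k_neighbors,
                            seed = seed)
    return(cohort_rbind(cohort, synth, name = "dataset3"))
  }
  # per-class option: scale each class cell up proportionally, remainder to the
  # larger cell, keeping the total at exact sex parity
  grp <- cohort_rows(cohort, cohort$sex == rare)
  cls_counts <- table(factor(grp$disease, levels = c(0, 1)))
  n0 <- round(n_new_total * cls_counts[["0"]] / nrow(grp))
  n_per <- c("0" = n0, "1" = n_new_total - n0)
  out <- cohort
  for (cl in c("0", "1")) {
    if (n_per[[cl]] == 0) next
    cell <- cohort_rows(cohort, cohort$sex == rare & cohort$disease == as.numeric(cl))
    synth <- smote_generate(cell, n_per[[cl]], k_neighbors = k_neighbors,
                            seed = if (is.null(seed)) NULL else seed + as.integer(cl))
    out <- cohort_rbind(out, synth, name = "dataset3")
  }
  out
}

#' Split a cohort into training and test sets
#'
#' Random disjoint partition with `|test| = round(test_fraction * n)`. With
#' `sex_balanced_training = TRUE`, the training set is instead formed by
#' drawing equal-size random subsets from the males and females remaining
#' after the test draw and appending them (the size is the smaller sex's
#' count), mirroring the sex-balanced-training policy. The split is redrawn
#' (up to `max_retries` times) until both sexes and both classes appear in the
#' test set.
#'
#' @param cohort a recoded cohort.
#' @param test_fraction held-out proportion (default 0.30).
#' @param sex_balanced_training draw equal per-sex training subsets.
#' @param seed RNG seed.
#' @param max_retries bounded redraws for degenerate test folds (default 20).
#' @return list with cohorts `train` and `test`.
#' @export
train_test_split <- function(cohort, test_fraction = 0.30,
                             sex_balanced_training = FALSE, seed = NULL,
                             max_retries = 20) {
  validate_cohort(cohort)
  if (!is_recoded(cohort)) stop("recode the target before splitting")
  stopifnot(test_fraction > 0, test_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  n_test <- round(test_fraction * n)
  if (n_test < 1 || n_test >= n) stop("split error: cohort too small")

  for (attempt in seq_len(max_retries + 1)) {
    test_idx <- sample.int(n, n_test)
    test <- cohort_rows(cohort, test_idx)
    ok <- all(SEX_LEVELS %in% test$sex) && all(c(0, 1) %in% test$disease)
    if (ok) {
      train_pool <- cohort_rows(cohort, -test_idx)
      if (!sex_balanced_training) return(list(train = train_pool, test = test))
      f_idx <- which(train_pool$sex == "female")
      m_idx <- which(train_pool$sex == "male")
      k <- min(length(f_idx), length(m_idx))
      if (k < 2) next
      keep <- c(sample(f_idx, k), sample(m_idx, k))
      return(list(train = cohort_rows(train_pool, keep), test = test))
    }
  }
  stop("split error: could not draw a test set containing both sexes and both classes")
}
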