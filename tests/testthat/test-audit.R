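test_that("confusion tallies match hand enumeration", {
  truth <- c(1, 1, 0, 0, 1); pred <- c(1, 0, 0, 1, 1)
  cc <- confusion_from_predictions(truth, pred)
  expect_equal(unclass(cc)[c("tp", "fn", "tn", "fp")],
               list(tp = 2, fn = 1, tn = 1, fp = 1))

  perfect <- confusion_from_predictions(truth, truth)
  expect_equal(perfect$fp + perfect$fn, 0)
  inverted <- confusion_from_predictions(truth, 1 - truth)
  expect_equal(inverted$tp + inverted$tn, 0)
  expect_error(confusion_from_predictions(c(0, 1), c(1)), "length mismatch")
})

test_that("metric formulas match hand values and leave zero denominators undefined", {
  m <- metrics_from_confusion(confusion_from_predictions(c(1, 1, 0, 0), c(1, 0, 0, 1)))
  expect_equal(unname(m["accuracy"]), 0.5)

  cc <- structure(list(tp = 3, fn = 1, fp = 0, tn = 0), class = "confusion_counts")
  m2 <- metrics_from_confusion(cc)
  expect_equal(unname(m2["recall"]), 0.75)
  expect_equal(unname(m2["precision"]), 1.0)
  expect_equal(unname(m2["f_score"]), 6 / 7)
  expect_true(is.na(m2["tnr"]))  # tn + fp = 0: undefined, not 0

  all1 <- metrics_from_confusion(
    structure(list(tp = 4, tn = 3, fp = 0, fn = 0), class = "confusion_counts"))
  expect_equal(unname(all1[c("accuracy", "precision", "recall", "f_score", "tnr")]),
               rep(1, 5))
})

test_that("rank AUC equals the exhaustive pair oracle, including pure ties", {
  expect_equal(rank_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(rank_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_true(is.na(rank_auc(c(1, 1), c(0.5, 0.7))))

  # 6-point mixed-tie fixture
  truth <- c(1, 1, 1, 0, 0, 0)
  scores <- c(0.7, 0.5, 0.5, 0.5, 0.2, 0.7)
  expect_equal(rank_auc(truth, scores), auc_pair_oracle(truth, scores))
})

test_that("paired t-test matches hand formula, stats::t.test, and degenerate rules", {
  m <- c(3, 5, 4, 6); f <- c(2, 5, 3, 3)
  out <- paired_ttest(m, f)
  d <- m - f
  expect_equal(out$t_statistic, mean(d) / (sd(d) / sqrt(4)))
  ref <- t.test(m, f, paired = TRUE)
  expect_equal(out$t_statistic, unname(ref$statistic))
  expect_equal(out$p_value, ref$p.value)

  same <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  degen <- paired_ttest(c(2, 3, 4), c(1, 2, 3))  # constant nonzero difference
  expect_equal(degen$p_value, 0)
  expect_true(degen$degenerate)

  # NA pairs dropped pairwise
  out2 <- paired_ttest(c(m, NA), c(f, 0.4))
  expect_equal(out2$n, 4)
})

test_that("paired t-test rejection is calibrated on independent null pairs", {
  # Monte-Carlo: n = 100 pairs of independent standard normals, 400 replicates
  set.seed(77)
  rejections <- sum(replicate(400, {
    paired_ttest(rnorm(100), rnorm(100))$p_value < 0.05
  }))
  env <- qbinom(c(0.005, 0.995), 400, 0.05)
  expect_gte(rejections, env[1])
  expect_lte(rejections, env[2])
})

test_that("disparity rows carry the exact mean difference and sign conventions", {
  d0 <- disparity(c(0.7, 0.8), c(0.7, 0.8), "accuracy")
  expect_equal(d0$disparity, 0)

  d5 <- disparity(c(0.75, 0.85, 0.65), c(0.70, 0.80, 0.60), "recall")
  expect_equal(d5$disparity, 5)  # constant +5pp
  expect_equal(d5$disparity, d5$male_mean - d5$female_mean)

  # fnr disparity is the negated recall disparity on the same runs
  rec_m <- c(0.9, 0.7, 0.8); rec_f <- c(0.6, 0.5, 0.7)
  dr <- disparity(rec_m, rec_f, "recall")
  dfn <- disparity(1 - rec_m, 1 - rec_f, "fnr")
  expect_equal(dfn$disparity, -dr$disparity)
  expect_equal(abs(dfn$t_statistic), abs(dr$t_statistic))
})

test_that("stratified evaluation partitions one prediction pass by sex", {
  cohort <- make_separable_cohort(n_per = 10, seed = 51)
  model <- fit_learner(cohort, "gaussian_nb")
  test <- make_separable_cohort(n_per = 8, seed = 52)
  ev <- stratified_evaluate(model, test)

  # confusion additivity: all = female + male, cell by cell
  for (cell in c("tp", "tn", "fp", "fn")) {
    expect_equal(ev$confusions$all[[cell]],
                 ev$confusions$female[[cell]] + ev$confusions$male[[cell]])
  }
  # hand partition oracle
  pred <- predict(model, test, type = "class")
  for (sx in c("female", "male")) {
    sel <- test$sex == sx
    cc <- confusion_from_predictions(test$disease[sel], pred[sel])
    expect_equal(ev$confusions[[sx]], cc)
  }

  # a sex-blind perfect model on sex-symmetric data: zero disparity rows
  met <- ev$metrics
  for (mname in c("accuracy", "recall", "precision")) {
    fm <- met$value[met$group == "female" & met$metric == mname]
    mm <- met$value[met$group == "male" & met$metric == mname]
    expect_equal(fm, mm, info = mname)  # both perfect here
  }
})

test_that("metric identities hold on every run and group of a real experiment", {
  g <- generate_cohort(ilpd_like_spec(seed = 53))
  cfg <- experiment_config(1, "gaussian_nb", n_runs = 4, seed = 9, tune = FALSE)
  res <- run_experiment(g$cohort, cfg)
  runs <- res$runs
  wide <- reshape(runs, idvar = c("run", "group"), timevar = "metric",
                  direction = "wide")
  ok <- !is.na(wide$value.recall)
  expect_equal(wide$value.fnr[ok], 1 - wide$value.recall[ok], tolerance = 1e-12)
  expect_equal(wide$value.tpr[ok], wide$value.recall[ok], tolerance = 1e-12)
  ok2 <- !is.na(wide$value.tnr)
  expect_equal(wide$value.fpr[ok2], 1 - wide$value.tnr[ok2], tolerance = 1e-12)
})

test_that("the experiment grid emits one table per cell and report files round-trip", {
  g <- generate_cohort(null_spec(n = 60, prevalence = 0.5, seed = 54))
  grid <- run_grid(g$cohort, experiments = c(1, 3),
                   learners = c("logistic_regression", "gaussian_nb"),
                   n_runs = 2, seed = 5, tune = FALSE)
  expect_length(grid, 4)
  expect_named(grid, c("exp1_logistic_regression", "exp1_gaussian_nb",
                       "exp3_logistic_regression", "exp3_gaussian_nb"))

  dir <- withr::local_tempdir()
  files <- write_report_tables(grid, dir)
  expect_length(files, 5)  # 4 disparity tables + master
  tab <- read.csv(file.path(dir, "disparity_exp1_gaussian_nb.csv"))
  expect_equal(nrow(tab), 9)
  expect_equal(tab$disparity, tab$male_mean - tab$female_mean)

  # master file reproduces every per-run value and recomputes the disparities
  master <- read.csv(file.path(dir, "per_run_metrics.csv"))
  sub <- master[master$table == "exp1_gaussian_nb", ]
  expect_equal(sub$value,
               grid$exp1_gaussian_nb$runs$value)
  for (met in c("accuracy", "recall")) {
    m <- sub$value[sub$group == "male" & sub$metric == met]
    f <- sub$value[sub$group == "female" & sub$metric == met]
    ok <- !is.na(m) & !is.na(f)
    expect_equal(100 * (mean(m[ok]) - mean(f[ok])),
                 tab$disparity[tab$metric == met], info = met)
  }
})

test_that("rfe experiments select exactly n_keep features per run", {
  g <- generate_cohort(ilpd_like_spec(seed = 55))
  cfg <- experiment_config(3, "logistic_regression", n_runs = 2, seed = 3,
                           tune = FALSE)
  res <- run_experiment(g$cohort, cfg)
  expect_true(all(lengths(res$selected_features) == 5))
  expect_true(all(unlist(res$selected_features) %in% feature_names()))
})

test_that("safe mode runs leakage-free end to end", {
  g <- generate_cohort(ilpd_like_spec(seed = 56, missing_rate = 0.02))
  cfg <- experiment_config(2, "logistic_regression", n_runs = 2, seed = 4,
                           tune = FALSE, mode = "safe")
  res <- run_experiment(g$cohort, cfg)
  expect_equal(max(res$runs$run), 2)
  expect_true(all(c("female", "male") %in% res$runs$group))
})
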