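test_that("mean imputation fills only missing cells with the observed mean", {
  cohort <- make_cell_cohort(3, 3, 3, 3, seed = 2)
  cohort$ag_ratio <- c(1.0, NA, 3.0, cohort$ag_ratio[4:12])
  out <- impute_mean(cohort)
  expect_equal(out$cohort$ag_ratio[2],
               mean(cohort$ag_ratio[-2], na.rm = TRUE))
  expect_equal(out$report$imputed_cells, 1L)
  expect_true(attr(out$cohort, "imputed"))
  # observed values untouched
  expect_equal(out$cohort$ag_ratio[-2], cohort$ag_ratio[-2])

  # hand-computed: 5 records, 2 missing -> mean of the 3 observed
  c5 <- make_cell_cohort(2, 1, 1, 1, seed = 3)
  c5$ag_ratio <- c(0.4, NA, 1.1, NA, 2.4)
  out5 <- impute_mean(c5)
  expect_equal(out5$cohort$ag_ratio, c(0.4, 1.3, 1.1, 1.3, 2.4))
  expect_equal(out5$report$imputed_cells, 2L)

  # no missing cells: identity, zero count
  clean <- make_cell_cohort(2, 2, 2, 2, seed = 4)
  outc <- impute_mean(clean)
  expect_equal(as.data.frame(outc$cohort)[names(clean)], as.data.frame(clean),
               ignore_attr = TRUE)
  expect_equal(outc$report$imputed_cells, 0L)

  # entirely-missing column has no mean
  allna <- make_cell_cohort(3, 3, 0, 0, seed = 5)
  allna$ag_ratio <- NA_real_
  expect_error(impute_mean(allna), "no observed values")

  # training-only scope: supplied statistics are used verbatim
  stats <- out5$report$fit_stats
  c2 <- make_cell_cohort(1, 1, 1, 1, seed = 6)
  c2$ag_ratio[1] <- NA
  applied <- impute_mean(c2, stats = stats)
  expect_equal(applied$cohort$ag_ratio[1], stats[["ag_ratio"]])
  expect_equal(applied$report$fit_scope, "training-only")
})

test_that("sex encoding is the fixed female=0 / male=1 map and keeps the factor", {
  f <- encode_sex(make_cell_cohort(4, 4, 0, 0))
  expect_true(all(f$sex_code == 0))
  m <- encode_sex(make_cell_cohort(0, 0, 4, 4))
  expect_true(all(m$sex_code == 1))
  mixed <- encode_sex(make_cell_cohort(3, 2, 5, 10))
  expect_equal(mean(mixed$sex_code), 15 / 20)
  expect_s3_class(mixed$sex, "factor")  # categorical field retained
  expect_equal(attr(mixed, "sex_encoding"), c(female = 0, male = 1))
})

test_that("target recoding maps selector 1 -> diseased and validates codes", {
  raw <- make_cell_cohort(1, 1, 1, 0, seed = 7)
  attr(raw, "recoded") <- FALSE
  raw$disease <- c(1, 2, 1)  # selector codes
  rec <- recode_target(raw)
  expect_equal(rec$disease, c(1L, 0L, 1L))
  expect_true(attr(rec, "recoded"))

  raw$disease <- c(2, 2, 2)
  expect_equal(recode_target(raw)$disease, c(0L, 0L, 0L))

  raw$disease <- c(1, 5, 2)
  expect_error(recode_target(raw), "Selector value 5")
})

test_that("min-max scaling matches hand computation and handles degenerate ranges", {
  cohort <- make_cell_cohort(1, 1, 1, 0, seed = 8)
  cohort$total_bilirubin <- c(0, 5, 10)
  cohort$albumin <- c(4, 4, 4)           # constant -> all zero, not an error
  cohort$age <- c(2, 3, 7)
  out <- minmax_scale(cohort)
  expect_equal(out$cohort$total_bilirubin, c(0, 0.5, 1))
  expect_equal(out$cohort$albumin, c(0, 0, 0))
  expect_equal(out$cohort$age, (c(2, 3, 7) - 2) / 5)
  expect_true(attr(out$cohort, "scaled"))

  # 4-value hand check of (x - min) / (max - min)
  c4 <- make_cell_cohort(1, 1, 1, 1, seed = 9)
  c4$ag_ratio <- c(0.3, 0.9, 1.5, 2.7)
  s4 <- minmax_scale(c4)$cohort
  expect_equal(s4$ag_ratio, c(0, 0.25, 0.5, 1))

  # all features end in [0, 1]
  g <- preprocess_cohort(generate_cohort(ilpd_like_spec(seed = 10))$cohort)$cohort
  for (col in c("age", biomarker_names())) {
    expect_true(all(g[[col]] >= 0 & g[[col]] <= 1), info = col)
  }
})

test_that("scaling is monotone and idempotent on already-scaled data", {
  cohort <- make_cell_cohort(5, 5, 5, 5, seed = 11)
  scaled <- minmax_scale(cohort)$cohort
  for (col in c("age", biomarker_names())) {
    expect_equal(order(scaled[[col]]), order(cohort[[col]]), info = col)
  }
  attr(scaled, "scaled") <- FALSE  # re-fit on the scaled data
  twice <- minmax_scale(scaled)$cohort
  for (col in c("age", biomarker_names())) {
    expect_equal(twice[[col]], scaled[[col]], tolerance = 1e-12, info = col)
  }
})

test_that("training-only scale parameters transfer to held-out data", {
  train <- make_cell_cohort(5, 5, 5, 5, seed = 12)
  test <- make_cell_cohort(3, 3, 3, 3, seed = 13)
  fit <- minmax_scale(train)
  applied <- minmax_scale(test, stats = fit$report$scale_params)
  sp <- fit$report$scale_params
  expect_equal(applied$cohort$total_bilirubin,
               (test$total_bilirubin - sp["total_bilirubin", "min"]) /
                 diff(sp["total_bilirubin", c("min", "max")]),
               ignore_attr = TRUE)
  expect_equal(applied$report$fit_scope, "training-only")
})
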