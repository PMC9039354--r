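test_that("SMOTE records are convex combinations of true k-nearest pairs with inherited labels", {
  group <- make_cell_cohort(0, 18, 0, 12, seed = 21)  # all diseased, mixed sex
  k <- 4
  synth <- smote_generate(group, n_new = 25, k_neighbors = k, seed = 99)
  expect_equal(nrow(synth), 25)
  expect_true(all(synth$provenance == "smote"))

  cols <- intersect(c("age", biomarker_names()), names(group))
  feats <- as.matrix(as.data.frame(group)[, cols])
  d <- as.matrix(stats::dist(feats))  # brute-force distance oracle
  seed_idx <- attr(synth, "seed_index")
  nbr_idx <- attr(synth, "neighbor_index")
  u <- attr(synth, "u")

  for (i in seq_len(nrow(synth))) {
    s <- seed_idx[i]; nb <- nbr_idx[i]
    # neighbour is within the k-nearest of the seed (ties allowed)
    kth <- sort(d[s, -s])[k]
    expect_lte(d[s, nb], kth + 1e-12)
    # exact interpolation x + u (x_nn - x); every value inside the segment box
    expect_equal(unlist(synth[i, cols]),
                 feats[s, ] + u[i] * (feats[nb, ] - feats[s, ]),
                 tolerance = 1e-12)
    expect_true(all(unlist(synth[i, cols]) >= pmin(feats[s, ], feats[nb, ]) - 1e-12))
    expect_true(all(unlist(synth[i, cols]) <= pmax(feats[s, ], feats[nb, ]) + 1e-12))
    # sex and label inherited from the seed record
    expect_equal(as.character(synth$sex[i]), as.character(group$sex[s]))
    expect_equal(synth$disease[i], group$disease[s])
  }

  # determinism given the seed
  again <- smote_generate(group, n_new = 25, k_neighbors = k, seed = 99)
  expect_identical(as.data.frame(synth), as.data.frame(again))

  expect_error(smote_generate(group[1:4, ], n_new = 2, k_neighbors = 5),
               "parameter error")
  expect_error(smote_generate(group, n_new = -1), "parameter error")
})

test_that("balance_classes reaches exact class parity without touching originals", {
  cohort <- make_cell_cohort(3, 6, 1, 4, seed = 22)  # 4 healthy / 10 diseased
  out <- balance_classes(cohort, k_neighbors = 2, seed = 5)
  s <- summarize_cohort(out)
  expect_equal(unname(s$class_totals), c(10, 10))
  expect_equal(s$total, 14 + 6)
  # originals preserved exactly, in place
  expect_equal(as.data.frame(out)[1:14, names(cohort)], as.data.frame(cohort),
               ignore_attr = TRUE)
  expect_equal(sum(out$provenance == "smote"), 6)
  # synthetic records all carry the minority class
  expect_true(all(out$disease[out$provenance == "smote"] == 0))

  # already balanced -> identity
  bal <- make_cell_cohort(5, 5, 5, 5, seed = 23)
  expect_identical(as.data.frame(balance_classes(bal)), as.data.frame(bal))
})

test_that("balance_sexes reaches exact sex parity; synthetic class mix follows sampled seeds", {
  cohort <- make_cell_cohort(2, 4, 6, 8, seed = 24)  # 6 F / 14 M
  out <- balance_sexes(cohort, k_neighbors = 3, seed = 11)
  s <- summarize_cohort(out)
  expect_equal(unname(s$sex_totals), c(14, 14))
  expect_equal(s$total, 28)
  synth <- out[out$provenance == "smote", ]
  expect_equal(nrow(synth), 8)
  expect_true(all(synth$sex == "female"))

  # label inheritance: class mix of synthetic females equals the empirical mix
  # of the seed records drawn under this RNG seed
  females <- cohort[cohort$sex == "female", ]
  ref <- smote_generate(females, n_new = 8, k_neighbors = 3, seed = 11)
  expect_equal(synth$disease, females$disease[attr(ref, "seed_index")])

  # sex-balanced input -> identity
  bal <- make_cell_cohort(5, 5, 4, 6, seed = 25)
  expect_identical(as.data.frame(balance_sexes(bal)), as.data.frame(bal))

  # per-class option also reaches parity
  pc <- balance_sexes(make_cell_cohort(6, 8, 20, 30, seed = 26),
                      k_neighbors = 3, seed = 12, within_class = TRUE)
  expect_equal(unname(summarize_cohort(pc)$sex_totals), c(50, 50))
})

test_that("train/test split honours fraction, disjointness and representation", {
  cohort <- make_cell_cohort(20, 20, 30, 30, seed = 27)
  sp <- train_test_split(cohort, test_fraction = 0.3, seed = 1)
  expect_equal(nrow(sp$test), 30)
  expect_equal(nrow(sp$train), 70)
  expect_true(all(c("female", "male") %in% sp$test$sex))
  expect_true(all(c(0, 1) %in% sp$test$disease))

  # same seed -> identical; different seed -> different (with high probability)
  sp2 <- train_test_split(cohort, test_fraction = 0.3, seed = 1)
  expect_identical(as.data.frame(sp$test), as.data.frame(sp2$test))
  sp3 <- train_test_split(cohort, test_fraction = 0.3, seed = 2)
  expect_false(identical(as.data.frame(sp$test), as.data.frame(sp3$test)))

  # sex-balanced training: equal per-sex training counts
  unb <- make_cell_cohort(30, 30, 70, 70, seed = 28)
  spb <- train_test_split(unb, test_fraction = 0.3, sex_balanced_training = TRUE,
                          seed = 3)
  expect_equal(sum(spb$train$sex == "female"), sum(spb$train$sex == "male"))

  # degenerate cohort cannot satisfy representation
  onesex <- make_cell_cohort(10, 10, 0, 0, seed = 29)
  expect_error(train_test_split(onesex, seed = 1), "split error")
})
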