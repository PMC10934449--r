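test_that("stratified folds partition every row with near-equal sizes", {
  y <- rep(c("HC", "PD"), each = 200)
  fold <- stratified_folds(y, 5, seed = 4)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(as.numeric(table(fold)), rep(80, 5))
  for (f in 1:5)
    expect_equal(as.numeric(table(y[fold == f])), c(40, 40))
  expect_identical(fold, stratified_folds(y, 5, seed = 4))
})

test_that("nested CV partitions outer folds correctly on a 400-row table", {
  df <- make_gauss_features(200, sep = 6, seed = 2)
  fit <- nested_cv_train(df, model_spec("knn1"), cv_config(seed = 2))
  sizes <- vapply(fit$outer_folds, length, integer(1))
  expect_equal(sizes, rep(80, 5))
  expect_equal(sort(unlist(fit$outer_folds)), seq_len(400))
})

test_that("all families are deterministic given the seed", {
  df <- make_gauss_features(40, sep = 4, seed = 9)
  te <- make_gauss_features(20, sep = 4, seed = 10)
  for (fam in c("cubic_svm", "knn1", "wide_nn")) {
    f1 <- nested_cv_train(df, model_spec(fam), cv_config(seed = 11))
    f2 <- nested_cv_train(df, model_spec(fam), cv_config(seed = 11))
    expect_identical(f1$per_fold, f2$per_fold)
    expect_identical(predict_model(f1$fit, as.matrix(te[, f1$cols])),
                     predict_model(f2$fit, as.matrix(te[, f2$cols])))
  }
})

test_that("evaluate reproduces the hand-computed confusion metrics", {
  ## 1-NN on coincident points forces an exact confusion matrix:
  ## TP 9, FN 1, TN 8, FP 2
  train <- make_gauss_features(10, sep = 30, seed = 3)
  fit <- nested_cv_train(train, model_spec("knn1"),
                         cv_config(k_outer = 2, k_inner = 2, seed = 3))
  hc_rows <- train[train$label == "HC", ]
  pd_rows <- train[train$label == "PD", ]
  test <- rbind(pd_rows[1:9, ],      # predicted PD, truly PD -> 9 TP
                hc_rows[1, ],        # predicted HC
                hc_rows[2:9, ],      # predicted HC, truly HC -> 8 TN
                pd_rows[10, ], pd_rows[10, ])  # predicted PD
  test$label <- c(rep("PD", 9), "PD",            # the HC-located row: FN
                  rep("HC", 8), "HC", "HC")      # the PD-located rows: FP
  rep <- evaluate(fit, test)
  expect_equal(rep$sensitivity, 0.9)
  expect_equal(rep$specificity, 0.8)
  expect_equal(rep$test_accuracy, 0.85)
  expect_equal(rep$f1, 18 / 21)
  expect_equal(sum(rep$confusion), 20)

  perfect <- rbind(pd_rows[1:5, ], hc_rows[1:5, ])
  repf <- evaluate(fit, perfect)
  expect_equal(repf$test_accuracy, 1)
  expect_equal(repf$f1, 1)
  expect_equal(as.numeric(diag(repf$confusion)), c(5, 5))

  onesided <- pd_rows[1:5, ]
  expect_error(evaluate(fit, onesided), "both classes")
})

test_that("accuracy decomposes into sensitivity and specificity", {
  df <- make_gauss_features(40, sep = 3, seed = 21)
  te <- make_gauss_features(25, sep = 3, seed = 22)
  fit <- nested_cv_train(df, model_spec("cubic_svm"), cv_config(seed = 21))
  rep <- evaluate(fit, te)
  P <- sum(te$label == "PD"); N <- sum(te$label == "HC")
  expect_equal(rep$test_accuracy,
               (rep$sensitivity * P + rep$specificity * N) / (P + N))
})

test_that("1-NN prediction agrees with class::knn on tie-free data", {
  tr <- make_gauss_features(30, sep = 2, seed = 5)
  te <- make_gauss_features(15, sep = 2, seed = 6)
  cols <- feature_columns(tr)
  fit <- fit_model("knn1", as.matrix(tr[, cols]),
                   factor(tr$label, c("HC", "PD")), NA, 1)
  mine <- predict_model(fit, as.matrix(te[, cols]))
  ref <- class::knn(as.matrix(tr[, cols]), as.matrix(te[, cols]),
                    factor(tr$label, c("HC", "PD")), k = 1)
  expect_equal(as.character(mine), as.character(ref))
})

test_that("feature-set runs only touch their own columns", {
  df <- make_gauss_features(40, sep = 5, seed = 7)
  df_poisoned <- df
  df_poisoned[feature_columns(df, "gtcc")] <- NA_real_
  fit <- nested_cv_train(df_poisoned, model_spec("knn1"),
                         cv_config(seed = 7),
                         cols = feature_columns(df, "mfcc"))
  expect_gt(fit$outer_cv_accuracy, 0.9)
})

test_that("the suite covers the three-by-three configuration grid", {
  tr <- make_gauss_features(30, sep = 6, seed = 12)
  te <- make_gauss_features(10, sep = 6, seed = 13)
  suite <- run_model_suite(tr, te, cv_config(k_outer = 3, k_inner = 3, seed = 12))
  expect_equal(nrow(suite$summary), 9)
  expect_setequal(unique(suite$summary$feature_set), c("mfcc", "gtcc", "combined"))
  expect_setequal(unique(suite$summary$family), c("cubic_svm", "knn1", "wide_nn"))
  expect_named(suite$summary[1:7],
               c("feature_set", "family", "training_accuracy", "test_accuracy",
                 "sensitivity", "specificity", "f1"))
  suite2 <- run_model_suite(tr, te, cv_config(k_outer = 3, k_inner = 3, seed = 12))
  expect_identical(suite$summary, suite2$summary)
})

test_that("knn1 records its degenerate inner loop", {
  df <- make_gauss_features(30, sep = 4, seed = 8)
  fit <- nested_cv_train(df, model_spec("knn1"), cv_config(seed = 8))
  expect_true(is.na(fit$chosen_hyper))
  expect_true(all(vapply(fit$inner_folds, length, integer(1)) == 0))
})
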