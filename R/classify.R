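#' Classifier family specification
#'
#' The three fixed model families and their small inner-loop grids:
#' * `cubic_svm` — support-vector machine with polynomial kernel of degree
#'   3 under a one-vs-one decision scheme (which degenerates to a single
#'   binary machine for two classes); tunable margin-penalty constant
#'   `cost` over \{0.1, 1, 10\}.
#' * `knn1` — 1-nearest-neighbour, Euclidean metric; nothing tunable, so
#'   the inner loop degenerates (recorded as such in the report).
#' * `wide_nn` — one hidden layer of 100 rectified units with softmax
#'   output; tunable ridge (weight-decay) penalty over \{1e-4, 1e-2, 1\}.
#'
#' @param family `"cubic_svm"`, `"knn1"` or `"wide_nn"`.
#' @return An object of class `model_spec` with the family's grid.
#' @export
model_spec <- function(family = c("cubic_svm", "knn1", "wide_nn")) {
  family <- match.arg(family)
  grid <- switch(family,
    cubic_svm = c(0.1, 1, 10),
    knn1 = NA_real_,
    wide_nn = c(1e-4, 1e-2, 1))
  structure(list(family = family, grid = grid), class = "model_spec")
}

fit_model <- function(family, x, y, hyper, seed = 1L) {
  y <- factor(y, levels = c("HC", "PD"))
  switch(family,
    cubic_svm = structure(
      list(svm = e1071::svm(x, y, kernel = "polynomial", degree = 3,
                            coef0 = 1, cost = hyper, scale = FALSE)),
      class = "pdv_svm"),
    knn1 = structure(list(x = x, y = y), class = "pdv_knn1"),
    wide_nn = {
      size <- 100L
      d <- ncol(x)
      init <- with_seed(seed, list(
        W1 = matrix(rnorm(d * size, 0, sqrt(2 / d)), d, size),
        W2 = matrix(rnorm(size * 2L, 0, sqrt(2 / size)), size, 2L)))
      Y <- cbind(HC = as.numeric(y == "HC"), PD = as.numeric(y == "PD"))
      wts <- widenn_train_cpp(x, Y, init$W1, numeric(size), init$W2,
                              numeric(2L), decay = hyper, epochs = 200L,
                              lr = 0.01)
      structure(wts, class = "pdv_widenn")
    })
}

predict_model <- function(fit, x) UseMethod("predict_model")

#' @export
predict_model.pdv_svm <- function(fit, x) {
  factor(as.character(stats::predict(fit$svm, x)), levels = c("HC", "PD"))
}

#' @export
predict_model.pdv_knn1 <- function(fit, x) {
  ## vectorized Euclidean 1-NN; exact distance ties break toward the lowest
  ## class index (HC before PD)
  tr <- fit$x
  d2 <- outer(rowSums(x^2), rowSums(tr^2), `+`) - 2 * tcrossprod(x, tr)
  cls <- apply(d2, 1L, function(row) {
    cand <- which(row <= min(row) + 1e-12)
    levels(fit$y)[min(as.integer(fit$y[cand]))]
  })
  factor(cls, levels = levels(fit$y))
}

#' @export
predict_model.pdv_widenn <- function(fit, x) {
  H <- pmax(sweep(x %*% fit$W1, 2L, as.numeric(fit$b1), `+`), 0)
  O <- sweep(H %*% fit$W2, 2L, as.numeric(fit$b2), `+`)
  ## tie in the output scores goes to the lowest class index
  factor(ifelse(O[, 2L] > O[, 1L], "PD", "HC"), levels = c("HC", "PD"))
}

#' Cross-validation configuration
#'
#' @param k_outer,k_inner outer and inner fold counts (default 5 and 5);
#'   folds are stratified by class.
#' @param seed integer seed for fold assignment and model initialization.
#' @param positive_class class treated as positive in sensitivity/F1
#'   (default `"PD"`).
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(k_outer = 5L, k_inner = 5L, seed = 1L,
                      positive_class = "PD") {
  if (k_outer < 2L || k_inner < 2L) stop("fold counts must be >= 2")
  structure(list(k_outer = as.integer(k_outer), k_inner = as.integer(k_inner),
                 seed = as.integer(seed), positive_class = positive_class),
            class = "cv_config")
}

#' Seeded stratified fold assignment
#'
#' Partitions indices into `k` folds with per-class balance; fold sizes
#' differ by at most one within each class.
#'
#' @param y class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids (1..k), one per element of `y`.
#' @export
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < k) stop("class ", cl, " has fewer rows than folds")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  })
  fold
}

#' Nested cross-validated training
#'
#' Outer stratified folds estimate generalization; on each outer-train
#' portion an inner stratified CV grid-search picks the family's
#' hyperparameter (ties toward the smallest value). The final model is
#' refit on the full training table with the majority-vote choice across
#' outer folds. The held-out test table is never seen here. Deterministic
#' given `cv$seed`.
#'
#' @param train feature data.frame with a `label` column.
#' @param model a [model_spec].
#' @param cv a [cv_config].
#' @param cols feature columns to use (default: all cepstral columns).
#' @return An object of class `cv_fit`: the refit model plus
#'   `training_accuracy` (mean outer-fold training-portion accuracy),
#'   `outer_cv_accuracy` (mean outer validation accuracy),
#'   `outer_confusion` (aggregate over outer validation folds),
#'   `per_fold`, `chosen_hyper`, `outer_folds`, `inner_folds`.
#' @export
nested_cv_train <- function(train, model, cv, cols = feature_columns(train)) {
  stopifnot(inherits(model, "model_spec"), inherits(cv, "cv_config"))
  x <- as.matrix(train[, cols, drop = FALSE])
  y <- factor(train$label, levels = c("HC", "PD"))
  if (any(is.na(y))) stop("labels must be HC or PD")
  outer_fold <- stratified_folds(y, cv$k_outer, cv$seed)
  grid <- model$grid
  tunable <- model$family != "knn1"
  per_fold <- data.frame(fold = seq_len(cv$k_outer), hyper = NA_real_,
                         train_accuracy = NA_real_, val_accuracy = NA_real_)
  inner_folds <- vector("list", cv$k_outer)
  conf <- matrix(0L, 2L, 2L, dimnames = list(truth = c("HC", "PD"),
                                             pred = c("HC", "PD")))
  for (f in seq_len(cv$k_outer)) {
    tr <- which(outer_fold != f); va <- which(outer_fold == f)
    if (length(unique(y[va])) < 2L || length(unique(y[tr])) < 2L)
      stop("a fold contains a single class; enlarge the table or reduce k")
    best <- grid[1L]
    if (tunable && length(grid) > 1L) {
      inner <- stratified_folds(y[tr], cv$k_inner, derive_seed(cv$seed, f))
      inner_folds[[f]] <- lapply(seq_len(cv$k_inner),
                                 function(g) tr[inner == g])
      score <- vapply(grid, function(h) {
        accs <- vapply(seq_len(cv$k_inner), function(g) {
          itr <- tr[inner != g]; iva <- tr[inner == g]
          fit <- fit_model(model$family, x[itr, , drop = FALSE], y[itr], h,
                           seed = derive_seed(cv$seed, 10L * f + g))
          mean(predict_model(fit, x[iva, , drop = FALSE]) == y[iva])
        }, numeric(1))
        mean(accs)
      }, numeric(1))
      best <- grid[which.max(score)]  # first max -> smallest on a sorted grid
    } else {
      inner_folds[[f]] <- list()
    }
    fit <- fit_model(model$family, x[tr, , drop = FALSE], y[tr], best,
                     seed = derive_seed(cv$seed, 1000L + f))
    pred_va <- predict_model(fit, x[va, , drop = FALSE])
    per_fold$hyper[f] <- best
    per_fold$train_accuracy[f] <-
      mean(predict_model(fit, x[tr, , drop = FALSE]) == y[tr])
    per_fold$val_accuracy[f] <- mean(pred_va == y[va])
    conf <- conf + table(truth = y[va], pred = pred_va)
  }
  hy <- per_fold$hyper
  chosen <- if (tunable) {
    tab <- table(hy)
    as.numeric(names(tab)[tab == max(tab)])[1L]  # majority, ties -> smallest
  } else NA_real_
  final <- fit_model(model$family, x, y, chosen,
                     seed = derive_seed(cv$seed, 9999L))
  structure(list(fit = final, family = model$family, chosen_hyper = chosen,
                 per_fold = per_fold,
                 training_accuracy = mean(per_fold$train_accuracy),
                 outer_cv_accuracy = mean(per_fold$val_accuracy),
                 outer_confusion = conf,
                 outer_folds = lapply(seq_len(cv$k_outer),
                                      function(f) which(outer_fold == f)),
                 inner_folds = inner_folds, cols = cols, cv = cv),
            class = "cv_fit")
}

#' Evaluate a fitted model on the held-out test table
#'
#' Accuracy = (TP+TN)/N, sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), F1 = 2TP/(2TP+FP+FN), with the disease class
#' positive.
#'
#' @param fit a [nested_cv_train] result.
#' @param test feature data.frame (already normalized with the training
#'   statistics).
#' @param positive_class positive label (default from the fit's
#'   [cv_config]).
#' @return An object of class `cv_report` with `training_accuracy`,
#'   `test_accuracy`, `sensitivity`, `specificity`, `f1`, `confusion`
#'   (2x2, truth x prediction), `outer_confusion`, `n`.
#' @export
evaluate <- function(fit, test, positive_class = fit$cv$positive_class) {
  stopifnot(inherits(fit, "cv_fit"))
  y <- factor(test$label, levels = c("HC", "PD"))
  if (!all(c("HC", "PD") %in% y))
    stop("test table must contain both classes")
  pred <- predict_model(fit$fit, as.matrix(test[, fit$cols, drop = FALSE]))
  conf <- table(truth = y, pred = pred)
  pos <- positive_class; neg <- setdiff(c("HC", "PD"), pos)
  tp <- conf[pos, pos]; fn <- conf[pos, neg]
  tn <- conf[neg, neg]; fp <- conf[neg, pos]
  structure(list(family = fit$family, chosen_hyper = fit$chosen_hyper,
                 training_accuracy = fit$training_accuracy,
                 outer_cv_accuracy = fit$outer_cv_accuracy,
                 test_accuracy = (tp + tn) / sum(conf),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 f1 = 2 * tp / (2 * tp + fp + fn),
                 confusion = conf, outer_confusion = fit$outer_confusion,
                 n = sum(conf)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: train %.3f | outer-CV %.3f | test %.3f | sens %.3f | spec %.3f | F1 %.3f\n",
              x$family, x$training_accuracy, x$outer_cv_accuracy,
              x$test_accuracy, x$sensitivity, x$specificity, x$f1))
  invisible(x)
}

#' Run the full model grid: three families by three feature sets
#'
#' Mirrors the reported configuration grid: each family fit on MFCC-only
#' (13 columns), GTCC-only (13), and combined (26) features. z-score
#' statistics are fit on the training table only and applied to both
#' tables; each configuration's held-out test table is evaluated exactly
#' once.
#'
#' @param train,test feature data.frames sharing the cepstral column
#'   dialect (raw, not yet normalized).
#' @param cv a [cv_config].
#' @param families character vector of [model_spec] families.
#' @param feature_sets character vector among `"mfcc"`, `"gtcc"`,
#'   `"combined"`.
#' @return List: `summary` (one data.frame row per configuration, in the
#'   reported column order) and `reports` (the `cv_report` objects, named
#'   `<set>.<family>`).
#' @export
run_model_suite <- function(train, test, cv,
                            families = c("cubic_svm", "knn1", "wide_nn"),
                            feature_sets = c("mfcc", "gtcc", "combined")) {
  all_cols <- feature_columns(train)
  stats <- zscore_fit(train[, all_cols, drop = FALSE])
  train_n <- train; test_n <- test
  train_n[all_cols] <- zscore_apply(train[, all_cols, drop = FALSE], stats)
  test_n[all_cols] <- zscore_apply(test[, all_cols, drop = FALSE], stats)
  reports <- list()
  rows <- list()
  for (fs in feature_sets) {
    cols <- feature_columns(train, fs)
    for (fam in families) {
      fit <- nested_cv_train(train_n, model_spec(fam), cv, cols = cols)
      rep <- evaluate(fit, test_n)
      key <- paste(fs, fam, sep = ".")
      reports[[key]] <- rep
      rows[[key]] <- data.frame(
        feature_set = fs, family = fam,
        training_accuracy = rep$training_accuracy,
        test_accuracy = rep$test_accuracy,
        sensitivity = rep$sensitivity, specificity = rep$specificity,
        f1 = rep$f1, outer_cv_accuracy = rep$outer_cv_accuracy,
        chosen_hyper = rep$chosen_hyper)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, reports = reports, norm_stats = stats)
}

#' Serialize a suite result
#'
#' Writes the summary as a flat CSV (reported column order) and the full
#' reports, confusion matrices included, as JSON.
#'
#' @param suite a [run_model_suite] result.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_suite <- function(suite, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(suite$summary, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    payload <- lapply(suite$reports, function(r) {
      r$confusion <- unclass(as.matrix(r$confusion))
      r$outer_confusion <- unclass(as.matrix(r$outer_confusion))
      unclass(r)
    })
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv_path, json_path))
}
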