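clf_features <- function(X, y) {
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  dplyr::bind_cols(
    tibble::tibble(trial = seq_len(nrow(X)), label = y, band = "delta"),
    tibble::as_tibble(X)
  )
}

test_that("confusion metrics match hand-computed percentages", {
  m <- confusion_metrics(9, 8, 2, 1)
  expect_equal(m[["accuracy"]], 85)
  expect_equal(m[["sensitivity"]], 90)
  expect_equal(m[["specificity"]], 80)
  expect_equal(m[["f1"]], 100 * 18 / 21, tolerance = 1e-12)
  expect_false(attr(m, "degenerate"))
  # no positives at all -> sensitivity 0 and degenerate flag
  m0 <- confusion_metrics(0, 10, 0, 0)
  expect_equal(m0[["accuracy"]], 100)
  expect_equal(m0[["sensitivity"]], 0)
  expect_true(attr(m0, "degenerate"))
  expect_error(confusion_metrics(0, 0, 0, 0), "zero")
})

test_that("1-NN predictions follow nearest Euclidean neighbors exactly", {
  X_train <- rbind(c(0, 0), c(0, 1), c(10, 10), c(10, 11))
  y_train <- c("low", "low", "high", "high")
  X_test <- rbind(c(1, 0), c(9, 10), c(4, 4), c(6, 6))
  # standardization is monotone per axis, so neighbors are preserved here
  pred <- train_predict("knn", X_train, y_train, X_test)
  expect_equal(pred, c("low", "high", "low", "high"))
})

test_that("Fisher LDA separates two Gaussian clusters along the right axis", {
  withr::with_seed(5, {
    a <- cbind(rnorm(30, -2, 0.5), rnorm(30, 0, 2))
    b <- cbind(rnorm(30, 2, 0.5), rnorm(30, 0, 2))
  })
  X_train <- rbind(a, b)
  y_train <- rep(c("a", "b"), each = 30)
  X_test <- rbind(c(-2, 3), c(2, -3), c(-1.5, 0), c(1.5, 0))
  expect_equal(
    train_predict("lda", X_train, y_train, X_test),
    c("a", "b", "a", "b")
  )
})

test_that("classifiers reach ~100% on separated clusters via repeated_cv", {
  withr::with_seed(2, {
    X <- cbind(
      c(rnorm(20, -3, 0.3), rnorm(20, 3, 0.3)),
      matrix(rnorm(40 * 4), 40, 4)
    )
  })
  y <- rep(c("pleasant", "unpleasant"), each = 20)
  feats <- clf_features(X, y)
  for (clf in c("svm_rbf", "lda", "knn")) {
    r <- repeated_cv(feats,
      selector = "ttest", classifier = clf,
      n_top_features = 2, cv_folds = 5, cv_repeats = 2, seed = 1
    )
    expect_gte(r$summary$accuracy, 99)
    expect_equal(r$positive_class, "pleasant")
  }
})

test_that("pure-noise labels give chance-level accuracy", {
  withr::with_seed(11, {
    X <- matrix(rnorm(80 * 6), 80, 6)
  })
  y <- rep(c("a", "b"), each = 40)
  r <- repeated_cv(clf_features(X, y),
    selector = "ttest", classifier = "knn",
    n_top_features = 3, cv_folds = 10, cv_repeats = 5, seed = 4
  )
  expect_gt(r$summary$accuracy, 35)
  expect_lt(r$summary$accuracy, 65)
})

test_that("repeated_cv is deterministic under its seed", {
  withr::with_seed(8, X <- matrix(rnorm(40 * 5), 40, 5))
  y <- rep(c("a", "b"), 20)
  feats <- clf_features(X, y)
  r1 <- repeated_cv(feats,
    selector = "ttest", classifier = "knn",
    cv_folds = 5, cv_repeats = 3, seed = 7
  )
  r2 <- repeated_cv(feats,
    selector = "ttest", classifier = "knn",
    cv_folds = 5, cv_repeats = 3, seed = 7
  )
  expect_identical(r1$per_repeat, r2$per_repeat)
  r3 <- repeated_cv(feats,
    selector = "ttest", classifier = "knn",
    cv_folds = 5, cv_repeats = 3, seed = 8
  )
  expect_false(identical(r1$per_repeat, r3$per_repeat))
  expect_equal(nrow(tidy(r1)), 3)
  expect_equal(glance(r1)$accuracy, r1$summary$accuracy)
})

test_that("repeated_cv validates its inputs", {
  withr::with_seed(1, X <- matrix(rnorm(12 * 3), 12, 3))
  feats <- clf_features(X, rep(c("a", "b"), 6))
  expect_error(
    repeated_cv(feats, cv_folds = 10),
    "at least cv_folds"
  )
  multi <- dplyr::bind_rows(feats, dplyr::mutate(feats, band = "theta"))
  expect_error(repeated_cv(multi), "several bands")
  expect_error(
    repeated_cv(feats, cv_folds = 3, positive_class = "zzz"),
    "not among"
  )
  expect_error(train_predict("boost", X, rep(c("a", "b"), 6), X), "unknown")
  expect_error(train_predict("knn", X, rep("a", 12), X), "both classes")
})

test_that("eval reports serialize to CSV with an Average row and JSON", {
  withr::with_seed(3, X <- matrix(rnorm(40 * 4), 40, 4))
  y <- rep(c("a", "b"), each = 20)
  r <- repeated_cv(clf_features(X, y),
    selector = "ttest", classifier = "knn",
    cv_folds = 5, cv_repeats = 4, seed = 2
  )
  base <- file.path(withr::local_tempdir(), "eval")
  write_eval_report(r, base)
  csv <- read.csv(paste0(base, ".csv"))
  expect_equal(nrow(csv), 5)
  expect_equal(csv$row[5], "Average")
  expect_equal(csv$accuracy[5], r$summary$accuracy, tolerance = 1e-9)
  js <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(js$classifier, "knn")
  expect_equal(js$cv_repeats, 4)
  expect_equal(js$summary$accuracy, r$summary$accuracy, tolerance = 1e-9)
})
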