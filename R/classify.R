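#' Confusion-matrix metrics in percent
#'
#' `accuracy = (tp + tn) / total`, `sensitivity = tp / (tp + fn)`,
#' `specificity = tn / (tn + fp)`, `F1 = 2 tp / (2 tp + fp + fn)`, each
#' multiplied by 100. A ratio with zero denominator is reported as 0 and the
#' result carries `degenerate = TRUE`.
#'
#' @param tp,tn,fp,fn Confusion counts (their sum must be positive).
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   `f1`, with attribute `degenerate`.
#' @export
#' @examples
#' confusion_metrics(9, 8, 2, 1)
confusion_metrics <- function(tp, tn, fp, fn) {
  tp <- unname(tp)
  tn <- unname(tn)
  fp <- unname(fp)
  fn <- unname(fn)
  total <- tp + tn + fp + fn
  if (total <= 0) abort("confusion counts sum to zero")
  safe <- function(num, den) if (den > 0) num / den else 0
  degenerate <- (tp + fn) == 0 || (tn + fp) == 0 || (2 * tp + fp + fn) == 0
  out <- 100 * c(
    accuracy = (tp + tn) / total,
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    f1 = safe(2 * tp, 2 * tp + fp + fn)
  )
  attr(out, "degenerate") <- degenerate
  out
}

standardize_train_test <- function(X_train, X_test) {
  mu <- colMeans(X_train)
  s <- apply(X_train, 2, sd)
  s[s == 0] <- 1
  list(
    train = sweep(sweep(X_train, 2, mu), 2, s, "/"),
    test = sweep(sweep(X_test, 2, mu), 2, s, "/")
  )
}

fisher_lda_predict <- function(X_train, y_train, X_test) {
  classes <- sort(unique(y_train))
  a <- X_train[y_train == classes[1], , drop = FALSE]
  b <- X_train[y_train == classes[2], , drop = FALSE]
  mu_a <- colMeans(a)
  mu_b <- colMeans(b)
  Sw <- ((nrow(a) - 1) * stats::cov(a) + (nrow(b) - 1) * stats::cov(b)) /
    (nrow(a) + nrow(b) - 2)
  w <- tryCatch(solve(Sw, mu_b - mu_a), error = function(e) {
    warn("singular within-class covariance; using the pseudo-inverse")
    MASS::ginv(Sw) %*% (mu_b - mu_a)
  })
  w <- as.numeric(w)
  thr <- sum(w * (mu_a + mu_b)) / 2
  # bias from class priors (Fisher discriminant with Gaussian class model)
  thr <- thr - log(nrow(b) / nrow(a))
  proj <- as.numeric(X_test %*% w)
  ifelse(proj > thr, classes[2], classes[1])
}

svm_rbf_predict <- function(X_train, y_train, X_test, tune_cost = TRUE,
                            cost_grid = 10^seq(-2, 2, by = 1),
                            inner_folds = 5) {
  yf <- factor(y_train)
  cost <- 1
  if (tune_cost && length(cost_grid) > 1) {
    n <- nrow(X_train)
    folds <- make_stratified_folds(yf, min(inner_folds, min(table(yf))))
    acc <- vapply(cost_grid, function(cc) {
      correct <- 0
      for (f in seq_len(max(folds))) {
        tr <- folds != f
        if (length(unique(yf[tr])) < 2) next
        fit <- e1071::svm(X_train[tr, , drop = FALSE], yf[tr],
          kernel = "radial", gamma = 1, cost = cc, scale = FALSE
        )
        pred <- predict(fit, X_train[!tr, , drop = FALSE])
        correct <- correct + sum(pred == yf[!tr])
      }
      correct / n
    }, numeric(1))
    cost <- cost_grid[order(-acc, seq_along(cost_grid))[1]]
  }
  fit <- e1071::svm(X_train, yf,
    kernel = "radial", gamma = 1, cost = cost,
    scale = FALSE
  )
  as.character(predict(fit, X_test))
}

#' Train a classifier and predict test labels
#'
#' The three classifiers of the pipeline, each on features standardized
#' with the training-set mean and standard deviation:
#' * `svm_rbf` -- RBF-kernel SVM, kernel `K(a, b) = exp(-||a - b||^2 / s^2)`
#'   with the kernel scale fixed at `s = 1` (i.e. `gamma = 1`); the box
#'   constraint is tuned on the training data only, by an inner
#'   cross-validated search over a log-spaced grid `10^-2 .. 10^2`.
#' * `lda` -- Fisher's linear discriminant, no regularization; a singular
#'   within-class covariance falls back to the pseudo-inverse with a
#'   warning.
#' * `knn` -- single nearest neighbor, Euclidean distance, equal weights.
#'
#' @param classifier One of `"svm_rbf"`, `"lda"`, `"knn"`.
#' @param X_train,X_test Numeric feature matrices.
#' @param y_train Training labels (two classes).
#' @param tune_cost Logical; tune the SVM box constraint (default `TRUE`).
#' @return Character vector of predicted test labels.
#' @export
train_predict <- function(classifier, X_train, y_train, X_test,
                          tune_cost = TRUE) {
  if (length(unique(y_train)) < 2) {
    abort("training data must contain both classes")
  }
  std <- standardize_train_test(X_train, X_test)
  switch(classifier,
    svm_rbf = svm_rbf_predict(std$train, y_train, std$test, tune_cost),
    lda = fisher_lda_predict(std$train, y_train, std$test),
    knn = as.character(class::knn(std$train, std$test, factor(y_train), k = 1)),
    abort(sprintf("unknown classifier '%s'", classifier))
  )
}

# per-observation fold id, stratified by class
make_stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

pick_positive_class <- function(classes, positive_class = NULL) {
  if (!is.null(positive_class)) {
    if (!positive_class %in% classes) {
      abort(sprintf("positive class '%s' not among the labels", positive_class))
    }
    return(positive_class)
  }
  preferred <- c("pleasant", "DT", "high", "deep")
  hit <- intersect(preferred, classes)
  if (length(hit) > 0) hit[1] else sort(classes)[2]
}

#' Repeated stratified cross-validated evaluation
#'
#' The evaluation protocol of the pipeline: per repeat, a seeded stratified
#' fold assignment; inside each training fold only, feature ranking by the
#' chosen selector and selection of the top `n_top_features` (no selection
#' leakage into the test fold); classifier training and prediction; a
#' confusion matrix accumulated over the folds and converted to accuracy /
#' sensitivity / specificity / F1 per repeat. The report averages over
#' repeats.
#'
#' @param features Feature tibble with a `label` column (see
#'   [graph_features()]); when several bands are present, pass one band at a
#'   time (e.g. `dplyr::filter(features, band == "delta")`).
#' @param selector One of `"relieff"`, `"ttest"`, `"mrmr"`.
#' @param classifier One of `"svm_rbf"`, `"lda"`, `"knn"`.
#' @param n_top_features Features kept per training fold.
#' @param cv_folds,cv_repeats Folds and repeats (defaults 10 and 100).
#' @param seed Integer seed; repeat r uses `seed + r`.
#' @param positive_class Label counted as positive for sensitivity; default
#'   picks `pleasant`/`DT` when present, else the second label in sort
#'   order.
#' @param relieff_k ReliefF neighbor count.
#' @param tune_cost Tune the SVM box constraint per fold (default `TRUE`).
#' @return An `eval_report`: list with `per_repeat` (tibble of per-repeat
#'   metrics), `summary` (means across repeats), and provenance fields.
#'   [tidy()] returns the per-repeat tibble, [glance()] the one-row summary.
#' @export
repeated_cv <- function(features, selector = "relieff",
                        classifier = "svm_rbf", n_top_features = 20,
                        cv_folds = 10, cv_repeats = 100, seed = 1L,
                        positive_class = NULL, relieff_k = 10,
                        tune_cost = TRUE) {
  if ("band" %in% names(features) && length(unique(features$band)) > 1) {
    abort("features span several bands; filter to one band before repeated_cv()")
  }
  d <- features_to_xy(features)
  X <- d$X
  y <- d$y
  classes <- sort(unique(y))
  pos <- pick_positive_class(classes, positive_class)
  neg <- setdiff(classes, pos)
  if (min(table(y)) < cv_folds) {
    abort("each class needs at least cv_folds members")
  }
  n_top <- min(n_top_features, ncol(X))

  per_repeat <- vector("list", cv_repeats)
  for (r in seq_len(cv_repeats)) {
    rep_seed <- seed + r
    counts <- c(tp = 0, tn = 0, fp = 0, fn = 0)
    withr::with_seed(rep_seed, {
      folds <- make_stratified_folds(y, cv_folds)
      # stratification guarantees both classes in every training fold as
      # long as class counts >= cv_folds (checked above)
      for (f in seq_len(cv_folds)) {
        tr <- folds != f
        sc <- rank_matrix(X[tr, , drop = FALSE], y[tr],
          method = selector,
          k = relieff_k, n_select = n_top
        )
        top <- order(-sc, seq_along(sc))[seq_len(n_top)]
        pred <- train_predict(
          classifier,
          X[tr, top, drop = FALSE], y[tr],
          X[!tr, top, drop = FALSE],
          tune_cost = tune_cost
        )
        truth <- y[!tr]
        counts["tp"] <- counts["tp"] + sum(pred == pos & truth == pos)
        counts["tn"] <- counts["tn"] + sum(pred == neg & truth == neg)
        counts["fp"] <- counts["fp"] + sum(pred == pos & truth == neg)
        counts["fn"] <- counts["fn"] + sum(pred == neg & truth == pos)
      }
    })
    m <- confusion_metrics(counts["tp"], counts["tn"], counts["fp"], counts["fn"])
    per_repeat[[r]] <- tibble::tibble(
      repeat_id = r, accuracy = m[["accuracy"]],
      sensitivity = m[["sensitivity"]],
      specificity = m[["specificity"]], f1 = m[["f1"]]
    )
  }
  per_repeat <- dplyr::bind_rows(per_repeat)
  structure(
    list(
      per_repeat = per_repeat,
      summary = dplyr::summarise(
        per_repeat,
        dplyr::across(c("accuracy", "sensitivity", "specificity", "f1"), mean)
      ),
      selector = selector, classifier = classifier,
      n_top_features = n_top, cv_folds = cv_folds,
      cv_repeats = cv_repeats, seed = seed,
      positive_class = pos, n_trials = nrow(X), n_features = ncol(X),
      subject_id = attr(features, "subject_id")
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<eval_report> %s + %s (top %d), %d-fold CV x %d\n",
    x$selector, x$classifier, x$n_top_features, x$cv_folds, x$cv_repeats
  ))
  cat(sprintf(
    "  accuracy %.1f%% | sensitivity %.1f%% | specificity %.1f%% | F1 %.1f%%\n",
    s$accuracy, s$sensitivity, s$specificity, s$f1
  ))
  invisible(x)
}

#' @rdname repeated_cv
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) x$per_repeat

#' @rdname repeated_cv
#' @export
glance.eval_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      selector = x$selector, classifier = x$classifier,
      n_top_features = x$n_top_features, cv_folds = x$cv_folds,
      cv_repeats = x$cv_repeats, seed = x$seed
    ),
    x$summary
  )
}

#' Write an evaluation report as CSV and JSON
#'
#' The CSV carries one row per repeat plus an `Average` row (accuracy,
#' sensitivity, specificity, F1 in percent); the JSON adds the full
#' configuration provenance.
#'
#' @param report An `eval_report`.
#' @param path Base path; `.csv` and `.json` are appended.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  per <- report$per_repeat
  avg <- dplyr::bind_cols(
    tibble::tibble(repeat_id = NA_integer_),
    report$summary
  )
  out <- dplyr::bind_rows(per, avg)
  out$row <- c(as.character(per$repeat_id), "Average")
  write.csv(
    out[, c("row", "accuracy", "sensitivity", "specificity", "f1")],
    paste0(path, ".csv"),
    row.names = FALSE
  )
  jsonlite::write_json(
    list(
      summary = report$summary, per_repeat = report$per_repeat,
      selector = report$selector, classifier = report$classifier,
      n_top_features = report$n_top_features, cv_folds = report$cv_folds,
      cv_repeats = report$cv_repeats, seed = report$seed,
      positive_class = report$positive_class,
      n_trials = report$n_trials, n_features = report$n_features
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
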