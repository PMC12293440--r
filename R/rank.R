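# Internal matrix-level rankers. Each returns per-feature scores; ordering
# (descending score, ties broken by feature index) happens in one place so
# all selectors share the same deterministic tie-break.

rank_from_scores <- function(scores, feature_names, method) {
  ord <- order(-scores, seq_along(scores))
  structure(
    tibble::tibble(
      feature = feature_names,
      score = scores,
      rank = match(seq_along(scores), ord)
    ),
    method = method,
    order = ord,
    class = c("feature_ranking", "tbl_df", "tbl", "data.frame")
  )
}

ttest_scores <- function(X, y) {
  classes <- sort(unique(y))
  stopifnot(length(classes) == 2)
  a <- X[y == classes[1], , drop = FALSE]
  b <- X[y == classes[2], , drop = FALSE]
  na <- nrow(a)
  nb <- nrow(b)
  stopifnot(na >= 2, nb >= 2)
  va <- apply(a, 2, var)
  vb <- apply(b, 2, var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  sp2 <- pmax(sp2, 1e-12) # variance floor for degenerate features
  abs(colMeans(a) - colMeans(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

relieff_scores <- function(X, y, k = 10) {
  n <- nrow(X)
  classes <- sort(unique(y))
  stopifnot(length(classes) == 2)
  if (any(table(y) <= k)) {
    abort(sprintf(
      "ReliefF with k = %d needs more than %d instances per class; reduce k",
      k, k
    ))
  }
  # min-max scale; constant features contribute no difference
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  Xs <- sweep(sweep(X, 2, rng[1, ]), 2, span, "/")
  D <- as.matrix(stats::dist(Xs))
  diag(D) <- Inf
  w <- numeric(ncol(X))
  for (i in seq_len(n)) {
    same <- which(y == y[i])
    same <- same[same != i]
    other <- which(y != y[i])
    hits <- same[order(D[i, same])[seq_len(k)]]
    misses <- other[order(D[i, other])[seq_len(k)]]
    dh <- abs(Xs[hits, , drop = FALSE] -
      matrix(Xs[i, ], k, ncol(X), byrow = TRUE))
    dm <- abs(Xs[misses, , drop = FALSE] -
      matrix(Xs[i, ], k, ncol(X), byrow = TRUE))
    w <- w + colMeans(dm) - colMeans(dh)
  }
  w / n
}

discretize_tertiles <- function(v) {
  qs <- unique(quantile(v, c(1 / 3, 2 / 3), names = FALSE, type = 7))
  findInterval(v, qs, left.open = TRUE) + 1L
}

mutual_info <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / outer(px, py)[pos]))
}

mrmr_scores <- function(X, y, n_select = ncol(X)) {
  p <- ncol(X)
  n_select <- min(n_select, p)
  disc <- apply(X, 2, discretize_tertiles)
  rel <- vapply(seq_len(p), function(j) mutual_info(disc[, j], y), numeric(1))
  selected <- integer(0)
  remaining <- seq_len(p)
  red_sum <- numeric(p)
  scores <- rep(-Inf, p)
  for (step in seq_len(n_select)) {
    crit <- if (length(selected) == 0) {
      rel[remaining]
    } else {
      rel[remaining] - red_sum[remaining] / length(selected)
    }
    pick <- remaining[order(-crit, remaining)[1]]
    scores[pick] <- n_select - step + 1 # rank-encoded: earlier pick, higher
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) == 0) break
    red_sum[remaining] <- red_sum[remaining] +
      vapply(remaining, function(j) mutual_info(disc[, j], disc[, pick]), numeric(1))
  }
  scores
}

rank_matrix <- function(X, y, method, k = 10, n_select = ncol(X)) {
  switch(method,
    ttest = ttest_scores(X, y),
    relieff = relieff_scores(X, y, k = k),
    mrmr = mrmr_scores(X, y, n_select = n_select),
    abort(sprintf("unknown selector '%s'", method))
  )
}

features_to_xy <- function(features, label_col = "label") {
  fcols <- feature_columns(features)
  X <- as.matrix(features[, fcols])
  storage.mode(X) <- "double"
  y <- as.character(features[[label_col]])
  if (anyNA(X)) abort("feature matrix contains missing values")
  if (length(unique(y)) != 2) abort("exactly two classes are required")
  list(X = X, y = y, feature_names = fcols)
}

#' Rank features by two-sample t statistic
#'
#' Pooled-variance two-sample t statistic per feature, ranked by absolute
#' value. Features with zero within-class variance use a pooled-variance
#' floor of 1e-12.
#'
#' @param features Feature tibble with a `label` column and feature columns
#'   (see [graph_features()]).
#' @return A `feature_ranking` tibble with columns `feature`, `score`,
#'   `rank` (1 = most discriminative); the descending order is stored in the
#'   `order` attribute, ties broken by feature index.
#' @export
ttest_rank <- function(features) {
  d <- features_to_xy(features)
  rank_from_scores(ttest_scores(d$X, d$y), d$feature_names, "ttest")
}

#' Rank features with ReliefF
#'
#' Standard ReliefF for two classes: for every instance, the k nearest
#' hits and k nearest misses (Euclidean distance on min-max-scaled
#' features); each feature's weight accumulates the mean absolute difference
#' to the misses minus that to the hits, averaged over all instances.
#'
#' @inheritParams ttest_rank
#' @param k Number of neighbors per class (default 10); every class must
#'   have more than `k` members.
#' @return A `feature_ranking` tibble (see [ttest_rank()]).
#' @export
relieff_rank <- function(features, k = 10) {
  d <- features_to_xy(features)
  rank_from_scores(relieff_scores(d$X, d$y, k = k), d$feature_names, "relieff")
}

#' Rank features with minimum-redundancy maximum-relevance (MRMR)
#'
#' Greedy selection maximizing mutual information with the label minus the
#' mean mutual information with already-selected features. Features are
#' discretized into tertiles; MI uses the plug-in estimator. The score
#' encodes pick order (earlier picks score higher); unpicked features score
#' `-Inf`.
#'
#' @inheritParams ttest_rank
#' @param n_select Number of greedy picks (default: all features).
#' @return A `feature_ranking` tibble (see [ttest_rank()]).
#' @export
mrmr_rank <- function(features, n_select = NULL) {
  d <- features_to_xy(features)
  if (is.null(n_select)) n_select <- ncol(d$X)
  rank_from_scores(
    mrmr_scores(d$X, d$y, n_select = n_select),
    d$feature_names, "mrmr"
  )
}
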