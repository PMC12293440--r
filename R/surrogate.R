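#' Surrogate graph ensemble
#'
#' Builds `n` surrogate graphs from a thresholded weighted graph by
#' degree-preserving edge rewiring (Maslov-Sneppen double edge swaps, 10
#' attempted swaps per edge by default) followed by random reassignment of
#' the original weight multiset to the rewired edges. Every surrogate
#' preserves node count, edge count, degree sequence and the multiset of
#' edge weights. When rewiring cannot move any edge (e.g. a star topology),
#' the surrogate falls back to a pure weight permutation and the fall-back
#' is counted in `n_fallback`.
#'
#' @param W_thr Thresholded symmetric weight matrix with >= 2 edges.
#' @param n Number of surrogates.
#' @param swaps_per_edge Attempted swaps per edge.
#' @param seed Integer seed (R RNG; same seed, same ensemble).
#' @return An object of class `surrogate_ensemble`: list with `graphs`
#'   (list of weight matrices), `sparsity_edges` (edge count), `n_fallback`,
#'   `seed`.
#' @export
surrogate_ensemble <- function(W_thr, n = 100, swaps_per_edge = 10, seed = 1L) {
  W_thr <- as_weight_matrix(W_thr)
  if (sum(W_thr[upper.tri(W_thr)] > 0) < 2) {
    abort("surrogate construction needs at least 2 edges")
  }
  if (n < 1) abort("n must be >= 1")
  graphs <- withr::with_seed(seed, {
    lapply(seq_len(n), function(i) rewire_once(W_thr, swaps_per_edge))
  })
  n_fallback <- sum(vapply(graphs, attr, logical(1), "fallback"))
  if (n_fallback > 0) {
    warn(sprintf(
      "%d surrogate(s) fell back to weight permutation (rewiring impossible)",
      n_fallback
    ))
  }
  structure(
    list(
      graphs = lapply(graphs, unclass), sparsity_edges = sum(W_thr > 0) / 2,
      n_fallback = n_fallback, seed = seed, swaps_per_edge = swaps_per_edge
    ),
    class = "surrogate_ensemble"
  )
}

# one rewired + weight-permuted surrogate (R-level, used by the exported
# ensemble API; the feature pipeline uses the batched C++ equivalent)
rewire_once <- function(W, swaps_per_edge) {
  n <- nrow(W)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  wts <- W[upper.tri(W) & W > 0]
  E <- nrow(idx)
  a <- idx[, 1]
  b <- idx[, 2]
  adj <- W > 0
  ok <- 0
  for (it in seq_len(swaps_per_edge * E)) {
    e <- sample.int(E, 2)
    p <- a[e[1]]
    q <- b[e[1]]
    r <- a[e[2]]
    t2 <- b[e[2]]
    if (runif(1) < 0.5) {
      tmp <- r
      r <- t2
      t2 <- tmp
    }
    if (p == t2 || r == q || p == r || q == t2) next
    if (adj[p, t2] || adj[r, q]) next
    adj[p, q] <- adj[q, p] <- FALSE
    adj[r, t2] <- adj[t2, r] <- FALSE
    adj[p, t2] <- adj[t2, p] <- TRUE
    adj[r, q] <- adj[q, r] <- TRUE
    a[e[1]] <- p
    b[e[1]] <- t2
    a[e[2]] <- r
    b[e[2]] <- q
    ok <- ok + 1
  }
  wp <- sample(wts)
  out <- matrix(0, n, n)
  out[cbind(a, b)] <- wp
  out[cbind(b, a)] <- wp
  dimnames(out) <- dimnames(W)
  attr(out, "fallback") <- ok == 0
  out
}

#' Surrogate z-score normalization of graph metrics
#'
#' For each metric component, `z = (m_orig - mean(m_surr)) / sd(m_surr)`.
#' Components whose surrogate standard deviation is 0 get `z = 0` with a
#' warning.
#'
#' @param original A `graph_metric_set` (variant `"raw"`).
#' @param ensemble_metrics List of `graph_metric_set`s for the surrogates
#'   (length >= 2).
#' @return A `graph_metric_set` with variant `"zscored"`.
#' @export
surrogate_zscore <- function(original, ensemble_metrics) {
  if (length(ensemble_metrics) < 2) {
    abort("surrogate z-scores need an ensemble of at least 2")
  }
  fields <- c(
    "strength", "clustering", "energy", "global_efficiency",
    "transitivity", "char_path_length"
  )
  out <- original
  any_zero_sd <- FALSE
  for (f in fields) {
    surr <- do.call(rbind, lapply(ensemble_metrics, function(m) as.numeric(m[[f]])))
    mu <- colMeans(surr)
    s <- apply(surr, 2, sd)
    z <- (as.numeric(original[[f]]) - mu) / s
    zero <- s == 0
    if (any(zero)) {
      any_zero_sd <- TRUE
      z[zero] <- 0
    }
    z[is.na(z)] <- 0
    names(z) <- names(original[[f]])
    out[[f]] <- if (length(z) == 1) unname(z) else z
  }
  if (any_zero_sd) {
    warn("zero surrogate standard deviation; affected z-scores set to 0")
  }
  out$variant <- "zscored"
  out$n_disconnected_pairs <- original$n_disconnected_pairs
  out
}

# z-scored metric vector (2C+4) for one connectivity matrix, via the batched
# C++ surrogate engine. Used by graph_features().
zscored_metric_vec <- function(W, sparsity, n_surrogates, swaps_per_edge = 10) {
  W_thr <- proportional_threshold(W, sparsity)
  C <- nrow(W_thr)
  orig <- graph_metrics_cpp(W_thr)[seq_len(2 * C + 4)]
  surr <- surrogate_metrics_cpp(W_thr, n_surrogates, swaps_per_edge)$metrics
  surr <- surr[, seq_len(2 * C + 4), drop = FALSE]
  mu <- colMeans(surr)
  s <- apply(surr, 2, sd)
  z <- (orig - mu) / s
  z[!is.finite(z)] <- 0
  z
}

#' Surrogate-normalized graph features from a coherence tensor
#'
#' For every (trial, component, band) connectivity matrix: proportional
#' thresholding at the configured sparsity, the six graph metrics on the
#' thresholded graph, the same metrics on `n_surrogates` rewired surrogates
#' (see [surrogate_ensemble()]), and z-score normalization of the original
#' against the ensemble. Features are then concatenated per trial over the
#' requested component combination, separately per band.
#'
#' @param ct A [coherence_tensor()].
#' @param component_combo Components whose feature blocks are concatenated
#'   (default: all components in the tensor).
#' @param sparsity Proportion of edges kept (default 0.3).
#' @param n_surrogates Ensemble size (default 100).
#' @param seed Integer seed for the surrogate RNG.
#' @param swaps_per_edge Rewiring effort per surrogate.
#' @return A tibble with columns `trial`, `label`, `band`, then
#'   `|combo| * (2 * C + 4)` feature columns named
#'   `component__metric__channel` (`component__metric` for the four global
#'   metrics): one row per trial and band, the band identified by the
#'   `band` column.
#' @export
graph_features <- function(ct, component_combo = ct$components,
                           sparsity = 0.3, n_surrogates = 100,
                           seed = 1L, swaps_per_edge = 10) {
  stopifnot(inherits(ct, "coherence_tensor"))
  missing <- setdiff(component_combo, ct$components)
  if (length(missing) > 0) {
    abort(paste(
      "components not present in the tensor:",
      paste(missing, collapse = ", ")
    ))
  }
  d <- dim(ct$values)
  C <- d[4]
  ch <- ct$montage$channel_names
  metric_names <- function(comp) {
    c(
      paste(comp, "strength", ch, sep = "__"),
      paste(comp, "clustering", ch, sep = "__"),
      paste(comp, c(
        "energy", "efficiency", "transitivity",
        "path_length"
      ), sep = "__")
    )
  }
  out <- vector("list", d[3])
  withr::with_seed(seed, {
    for (b in seq_len(d[3])) {
      feat <- matrix(
        0, d[1],
        length(component_combo) * (2 * C + 4)
      )
      nms <- character(0)
      col0 <- 0
      for (comp in component_combo) {
        k <- match(comp, ct$components)
        nms <- c(nms, metric_names(comp))
        for (tr in seq_len(d[1])) {
          W <- ct$values[tr, k, b, , ]
          diag(W) <- 0
          feat[tr, col0 + seq_len(2 * C + 4)] <-
            zscored_metric_vec(W, sparsity, n_surrogates, swaps_per_edge)
        }
        col0 <- col0 + 2 * C + 4
      }
      colnames(feat) <- nms
      out[[b]] <- dplyr::bind_cols(
        tibble::tibble(
          trial = seq_len(d[1]), label = ct$labels,
          band = ct$bands[b]
        ),
        tibble::as_tibble(feat)
      )
    }
  })
  dplyr::bind_rows(out)
}
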