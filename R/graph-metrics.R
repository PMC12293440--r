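as_weight_matrix <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) abort("weight matrix must be square")
  if (max(abs(W - t(W))) > 1e-9) abort("weight matrix must be symmetric")
  if (any(W < 0)) abort("weights must be non-negative")
  diag(W) <- 0
  W
}

#' Proportional thresholding of a weighted graph
#'
#' Retains the `ceiling(sparsity * n_pairs)` largest off-diagonal weights
#' and zeroes the rest, keeping the matrix symmetric. Ties at the cut are
#' broken by channel-pair lexicographic order (row-major upper triangle), so
#' the result is deterministic. Sparsity is typically swept over 0.1--0.3
#' in steps of 0.1.
#'
#' @param W Symmetric non-negative weight matrix (zero diagonal).
#' @param sparsity Proportion of edges kept, in (0, 1].
#' @return The thresholded weight matrix.
#' @export
#' @examples
#' W <- matrix(runif(25), 5, 5)
#' W <- (W + t(W)) / 2
#' diag(W) <- 0
#' sum(proportional_threshold(W, 0.3) > 0) / 2
proportional_threshold <- function(W, sparsity) {
  W <- as_weight_matrix(W)
  if (!(sparsity > 0 && sparsity <= 1)) abort("sparsity must lie in (0, 1]")
  n <- nrow(W)
  ut <- which(upper.tri(W))
  w <- W[ut]
  keep_n <- ceiling(sparsity * length(ut))
  if (length(unique(w)) == 1) {
    warn("all weights equal; proportional threshold is degenerate")
  }
  ord <- order(-w, ut) # descending weight, ties by pair order
  keep <- ut[ord[seq_len(keep_n)]]
  out <- matrix(0, n, n)
  out[keep] <- W[keep]
  out <- out + t(out)
  dimnames(out) <- dimnames(W)
  out
}

#' Node strength
#'
#' Weighted degree: `s_i = sum_j w_ij`.
#'
#' @param W Symmetric non-negative weight matrix.
#' @return Numeric vector of per-node strengths.
#' @export
node_strength <- function(W) {
  rowSums(as_weight_matrix(W))
}

#' Weighted clustering coefficient (Onnela)
#'
#' `C_i = (1 / (k_i (k_i - 1))) * sum_{j,h} (w'_ij w'_ih w'_jh)^(1/3)` on
#' max-normalized weights `w' = w / max(w)`; nodes of degree below 2 get 0.
#'
#' @param W Symmetric non-negative weight matrix.
#' @return Numeric vector of per-node clustering coefficients in \[0, 1\].
#' @export
weighted_clustering <- function(W) {
  W <- as_weight_matrix(W)
  m <- graph_metrics_cpp(W)
  n <- nrow(W)
  setNames(m[(n + 1):(2 * n)], rownames(W))
}

#' Weighted transitivity
#'
#' Global triangle-to-triplet ratio on max-normalized weights (same
#' normalization as [weighted_clustering()]); 0 when the graph has no
#' connected triplet.
#'
#' @param W Symmetric non-negative weight matrix.
#' @return Scalar in \[0, 1\].
#' @export
graph_transitivity <- function(W) {
  W <- as_weight_matrix(W)
  graph_metrics_cpp(W)[2 * nrow(W) + 3]
}

#' Characteristic path length
#'
#' Shortest-path distances on edge lengths `1/w`, averaged over ordered node
#' pairs with a finite distance. The number of disconnected (infinite) pairs
#' is attached as the `n_disconnected` attribute.
#'
#' @param W Symmetric non-negative weight matrix with at least one edge.
#' @return Scalar mean shortest path length.
#' @export
char_path_length <- function(W) {
  W <- as_weight_matrix(W)
  if (all(W == 0)) abort("characteristic path length is undefined for an edgeless graph")
  m <- graph_metrics_cpp(W)
  out <- m[2 * nrow(W) + 4]
  attr(out, "n_disconnected") <- as.integer(m[2 * nrow(W) + 5])
  out
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path distance
#' (`1 / Inf = 0`), distances from edge lengths `1/w`.
#'
#' @param W Symmetric non-negative weight matrix.
#' @return Scalar in \[0, 1\] for weights bounded by 1.
#' @export
global_efficiency <- function(W) {
  W <- as_weight_matrix(W)
  graph_metrics_cpp(W)[2 * nrow(W) + 2]
}

#' Graph energy
#'
#' Sum of the absolute eigenvalues of the weighted adjacency matrix.
#'
#' @param W Symmetric non-negative weight matrix.
#' @return Scalar energy.
#' @export
graph_energy <- function(W) {
  W <- as_weight_matrix(W)
  graph_metrics_cpp(W)[2 * nrow(W) + 1]
}

#' All six graph metrics of one weighted graph
#'
#' Computes the two local measures (per-node strength and Onnela clustering)
#' and the four global ones (energy, global efficiency, transitivity,
#' characteristic path length) in one pass.
#'
#' @param W Symmetric non-negative weight matrix.
#' @param variant Tag stored with the result (`"raw"` or `"zscored"`).
#' @return An object of class `graph_metric_set`: list with `strength`,
#'   `clustering` (per node), `energy`, `global_efficiency`, `transitivity`,
#'   `char_path_length`, `n_disconnected_pairs`, `variant`.
#' @export
graph_metric_set <- function(W, variant = "raw") {
  W <- as_weight_matrix(W)
  n <- nrow(W)
  m <- graph_metrics_cpp(W)
  structure(
    list(
      strength = setNames(m[1:n], rownames(W)),
      clustering = setNames(m[(n + 1):(2 * n)], rownames(W)),
      energy = m[2 * n + 1],
      global_efficiency = m[2 * n + 2],
      transitivity = m[2 * n + 3],
      char_path_length = m[2 * n + 4],
      n_disconnected_pairs = as.integer(m[2 * n + 5]),
      variant = variant
    ),
    class = "graph_metric_set"
  )
}

#' @export
print.graph_metric_set <- function(x, ...) {
  cat(sprintf(
    "<graph_metric_set> (%s) %d nodes | energy %.3g, efficiency %.3g, transitivity %.3g, path length %.3g\n",
    x$variant, length(x$strength), x$energy, x$global_efficiency,
    x$transitivity, x$char_path_length
  ))
  invisible(x)
}

#' @export
tidy.graph_metric_set <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      metric = "strength", channel = names(x$strength),
      value = unname(x$strength)
    ),
    tibble::tibble(
      metric = "clustering", channel = names(x$clustering),
      value = unname(x$clustering)
    ),
    tibble::tibble(
      metric = c(
        "energy", "global_efficiency", "transitivity",
        "char_path_length"
      ),
      channel = NA_character_,
      value = c(
        x$energy, x$global_efficiency, x$transitivity,
        x$char_path_length
      )
    )
  )
}
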