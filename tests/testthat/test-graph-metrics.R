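triangle <- function(ab = 1, ac = 1, bc = 1) {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- ab
  W[1, 3] <- W[3, 1] <- ac
  W[2, 3] <- W[3, 2] <- bc
  W
}

test_that("proportional thresholding keeps the top fraction of edges", {
  # 10-node full graph, sparsity 0.2 -> ceiling(0.2 * 45) = 9 edges
  withr::with_seed(1, {
    W <- matrix(runif(100, 0.01, 1), 10, 10)
    W <- (W + t(W)) / 2
    diag(W) <- 0
  })
  thr <- proportional_threshold(W, 0.2)
  expect_equal(sum(thr[upper.tri(thr)] > 0), 9)
  # kept edges are exactly the 9 largest
  kept <- sort(thr[upper.tri(thr)][thr[upper.tri(thr)] > 0])
  expect_equal(kept, sort(W[upper.tri(W)], decreasing = TRUE)[9:1])
  # sparsity 1 is the identity
  expect_equal(proportional_threshold(W, 1), W)
  # weights {0.9, 0.5, 0.1}, sparsity 1/3 -> only the 0.9 edge survives
  W3 <- triangle(0.9, 0.5, 0.1)
  t3 <- proportional_threshold(W3, 1 / 3)
  expect_equal(sort(unique(as.vector(t3))), c(0, 0.9))
  expect_error(proportional_threshold(W, 0))
})

test_that("node strength matches hand-computed row sums", {
  W <- triangle(0.5, 0.5, 1)
  expect_equal(node_strength(W), c(1, 1.5, 1.5))
  expect_equal(node_strength(matrix(0, 4, 4)), rep(0, 4))
  K4 <- matrix(1, 4, 4)
  diag(K4) <- 0
  expect_equal(node_strength(K4), rep(3, 4))
})

test_that("clustering and transitivity match the Onnela definitions", {
  expect_equal(weighted_clustering(triangle()), c(1, 1, 1))
  # star with 3 leaves: no triangles
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(weighted_clustering(star), rep(0, 4))
  expect_equal(graph_transitivity(star), 0)
  # uniform weights 0.5 normalize away
  expect_equal(weighted_clustering(triangle(0.5, 0.5, 0.5)), c(1, 1, 1))
  expect_equal(graph_transitivity(triangle()), 1)
  K4 <- matrix(1, 4, 4)
  diag(K4) <- 0
  expect_equal(weighted_clustering(K4), rep(1, 4))
  expect_equal(graph_transitivity(K4), 1)
})

test_that("path length and efficiency match exhaustive path enumeration", {
  expect_equal(as.numeric(char_path_length(triangle())), 1)
  # unit path a-b-c: distances (1, 1, 2) -> L = 4/3; efficiency 5/6
  path3 <- triangle(1, 0, 1)
  expect_equal(as.numeric(char_path_length(path3)), 4 / 3)
  expect_equal(global_efficiency(path3), mean(c(1, 1, 1 / 2)))
  expect_equal(global_efficiency(matrix(0, 3, 3)), 0)
  expect_error(char_path_length(matrix(0, 3, 3)), "edge")
  # two disjoint unit edges: L = 1, 8 of 12 ordered pairs disconnected
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 1
  L <- char_path_length(W)
  expect_equal(as.numeric(L), 1)
  expect_equal(attr(L, "n_disconnected"), 8)
  # unit K_n efficiency 1
  K5 <- matrix(1, 5, 5)
  diag(K5) <- 0
  expect_equal(global_efficiency(K5), 1)
})

test_that("graph energy matches eigenvalue sums", {
  K2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(graph_energy(K2), 2)
  expect_equal(graph_energy(triangle()), 4) # eigenvalues (2, -1, -1)
  expect_equal(graph_energy(matrix(0, 3, 3)), 0)
})

test_that("all six metrics match brute-force oracles on random graphs", {
  withr::with_seed(42, {
    for (rep in 1:100) {
      n <- sample(3:6, 1)
      W <- random_small_graph(n)
      if (sum(W > 0) < 2) next
      expect_all_equal(node_strength(W), oracle_strength(W))
      expect_all_equal(weighted_clustering(W), oracle_clustering(W))
      expect_all_equal(graph_transitivity(W), oracle_transitivity(W))
      expect_all_equal(graph_energy(W), oracle_energy(W))
      expect_all_equal(global_efficiency(W), oracle_efficiency(W))
      oc <- oracle_cpl(W)
      if (is.na(oc$cpl)) {
        expect_error(char_path_length(W))
      } else {
        L <- char_path_length(W)
        expect_all_equal(as.numeric(L), oc$cpl)
        expect_equal(attr(L, "n_disconnected"), oc$n_disconnected)
      }
    }
  })
})

test_that("metrics agree with igraph where igraph defines them", {
  skip_if_not_installed("igraph")
  withr::with_seed(7, {
    for (rep in 1:20) {
      W <- random_small_graph(6, p = 0.7)
      if (sum(W > 0) < 4) next
      g <- igraph::graph_from_adjacency_matrix(W,
        mode = "undirected", weighted = TRUE
      )
      expect_all_equal(node_strength(W), igraph::strength(g), 1e-9)
      # igraph's weighted transitivity ("barrat") differs; compare distances
      D <- floyd_distances_cpp(W)
      Dig <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
      expect_all_equal(D, Dig, 1e-9)
    }
  })
})

test_that("graph_metric_set bundles and tidies the metric panel", {
  W <- triangle(0.9, 0.6, 0.3)
  ms <- graph_metric_set(W)
  expect_s3_class(ms, "graph_metric_set")
  expect_equal(ms$strength, node_strength(W))
  expect_equal(ms$energy, graph_energy(W))
  expect_equal(ms$variant, "raw")
  td <- generics::tidy(ms)
  expect_true(all(c("metric", "channel", "value") %in% names(td)))
  expect_equal(nrow(td), 2 * 3 + 4)
})

test_that("degenerate weight matrices are rejected with clear errors", {
  expect_error(as_weight_matrix(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(as_weight_matrix(matrix(c(0, -1, -1, 0), 2, 2)), "negative")
  M <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_equal(diag(as_weight_matrix(M)), c(0, 0)) # diagonal zeroed
})
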