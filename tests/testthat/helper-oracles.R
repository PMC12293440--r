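# Independent brute-force oracles used to check the package implementations.
# Deliberately written with different algorithms than the package (recursive
# path enumeration instead of Floyd-Warshall, time-domain convolution instead
# of FFT, explicit loops instead of vectorized/matrix forms).

# ---- graph metric oracles (n <= ~7 nodes) ----

oracle_strength <- function(W) {
  n <- nrow(W)
  s <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) if (j != i) s[i] <- s[i] + W[i, j]
  }
  s
}

oracle_clustering <- function(W) {
  # Onnela et al. 2005: C_i = sum_{j,h} (w~_ij w~_ih w~_jh)^(1/3) / (k_i (k_i - 1))
  n <- nrow(W)
  mx <- max(W)
  if (mx <= 0) return(numeric(n))
  Wn <- W / mx
  k <- colSums(W > 0)
  C <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && h != j) {
          acc <- acc + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1 / 3)
        }
      }
    }
    C[i] <- acc / (k[i] * (k[i] - 1))
  }
  C
}

oracle_transitivity <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  if (mx <= 0) return(0)
  Wn <- W / mx
  k <- colSums(W > 0)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && h != j) {
          num <- num + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1 / 3)
        }
      }
    }
  }
  den <- sum(k * (k - 1))
  if (den == 0) 0 else num / den
}

oracle_energy <- function(W) sum(abs(eigen(W, symmetric = TRUE)$values))

# shortest path distances by exhaustive simple-path enumeration
oracle_distances <- function(W) {
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  walk <- function(path, cost) {
    i <- path[1]
    j <- path[length(path)]
    if (cost < best[i, j]) best[i, j] <<- cost
    for (nxt in seq_len(n)) {
      if (!(nxt %in% path) && is.finite(L[j, nxt])) {
        walk(c(path, nxt), cost + L[j, nxt])
      }
    }
  }
  for (i in seq_len(n)) walk(i, 0)
  best
}

oracle_efficiency <- function(W) {
  n <- nrow(W)
  if (n < 2) return(0)
  D <- oracle_distances(W)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_cpl <- function(W) {
  n <- nrow(W)
  D <- oracle_distances(W)
  off <- D[row(D) != col(D)]
  fin <- off[is.finite(off)]
  list(
    cpl = if (length(fin) == 0) NA_real_ else mean(fin),
    n_disconnected = sum(!is.finite(off))
  )
}

# random connected-ish weighted graph on n nodes
random_small_graph <- function(n, p = 0.6) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p) W[i, j] <- W[j, i] <- runif(1, 0.05, 1)
    }
  }
  W
}

# ---- naive time-domain Morlet CWT oracle ----

oracle_morlet_cwt <- function(x, fs, scales, omega0 = 6) {
  n <- length(x)
  dt <- 1 / fs
  out <- matrix(0 + 0i, length(scales), n)
  for (si in seq_along(scales)) {
    s <- scales[si]
    half <- min(n, ceiling(6 * s / dt))
    tt <- (-half:half) * dt
    psi <- pi^(-1 / 4) * exp(1i * omega0 * tt / s) * exp(-(tt / s)^2 / 2)
    # W(s, b) = sum_k x_k 1/sqrt(s) psi*((t_k - b)/s) dt
    for (b in seq_len(n)) {
      k <- (b - half):(b + half)
      keep <- k >= 1 & k <= n
      out[si, b] <- sum(x[k[keep]] * Conj(psi[keep]) / sqrt(s)) * dt
    }
  }
  out
}

# ---- misc ----

expect_all_equal <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(a - b)), tol)
}

make_test_epochs <- function(n_trials = 8, n_channels = 4, n_samples = 128,
                             fs = 128, seed = 1) {
  withr::with_seed(seed, {
    dat <- array(rnorm(n_trials * n_channels * n_samples),
      dim = c(n_trials, n_channels, n_samples)
    )
    epoch_set(
      dat,
      fs = fs, t0 = -200,
      labels = rep(c("pleasant", "unpleasant"), length.out = n_trials),
      montage = montage(paste0("ch", seq_len(n_channels)))
    )
  })
}
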