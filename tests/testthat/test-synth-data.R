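test_that("session design reproduces the cognitive trial mix", {
  d <- generate_session_design(seed = 1)
  expect_equal(nrow(d), 600)
  tab <- table(d$case)
  expect_equal(unname(tab[["NT"]]), 450)
  expect_equal(unname(tab[["ST"]]), 75)
  expect_equal(unname(tab[["DT"]]), 75)
  # degenerate mix
  d2 <- generate_session_design(
    n_runs = 1, trials_per_run = 4,
    mix = c(NT = 1), seed = 5
  )
  expect_equal(d2$case, rep("NT", 4))
  # determinism
  expect_identical(
    generate_session_design(seed = 42),
    generate_session_design(seed = 42)
  )
  expect_false(identical(
    generate_session_design(seed = 1)$case,
    generate_session_design(seed = 2)$case
  ))
  expect_error(generate_session_design(mix = c(NT = 0.7, ST = 0.2)), "sum to 1")
})

test_that("generator is deterministic and labels alternate", {
  spec <- generator_spec(n_trials_per_condition = 3, seed = 9)
  a <- generate_epochs(spec)
  b <- generate_epochs(spec)
  expect_identical(a$data, b$data)
  expect_equal(dim(a), c(6, 30, 300))
  expect_equal(a$fs, 250)
  expect_equal(a$t0, -200)
  expect_equal(a$labels, rep(c("pleasant", "unpleasant"), 3))
})

test_that("kappa = 1 coupling makes band-filtered channels near-identical", {
  cpl <- tibble::tibble(
    condition = rep(c("A", "B"), each = 1),
    band = "delta", chan_a = "c1", chan_b = "c2", kappa = c(1, 1)
  )
  spec <- generator_spec(
    n_trials_per_condition = 10,
    montage = montage(c("c1", "c2", "c3")),
    erp_peaks = tibble::tibble(
      latency_ms = numeric(),
      width_ms = numeric(), amplitude = numeric()
    ),
    coupling = cpl,
    band_sd = c(delta = 5),
    noise_sd = 1e-4,
    conditions = c("A", "B"), seed = 2
  )
  eps <- generate_epochs(spec)
  cc <- t(vapply(1:20, function(tr) {
    x <- bandpass(eps$data[tr, 1, ], 1, 4, fs = 250)
    y <- bandpass(eps$data[tr, 2, ], 1, 4, fs = 250)
    z <- bandpass(eps$data[tr, 3, ], 1, 4, fs = 250)
    c(coupled = cor(x, y), uncoupled = cor(x, z))
  }, numeric(2)))
  expect_gt(min(cc[, "coupled"]), 0.95)
  # the uncoupled channel is an independent process: much lower on average
  expect_lt(mean(abs(cc[, "uncoupled"])), 0.8)
})

test_that("zero coupling gap leaves conditions statistically identical", {
  # mean off-diagonal delta coherence per condition over many seeds
  diffs <- vapply(1:24, function(sd) {
    spec <- generator_spec(
      n_trials_per_condition = 2,
      montage = montage(c("a", "b", "c", "d")),
      coupling = tibble::tibble(
        condition = character(), band = character(),
        chan_a = character(), chan_b = character(), kappa = numeric()
      ),
      erp_peaks = tibble::tibble(
        latency_ms = 200, width_ms = 30, amplitude = 5
      ),
      band_sd = c(delta = 5), seed = sd
    )
    eps <- generate_epochs(spec)
    ct <- coherence_tensor(eps,
      windows = component_window("P300", 250, 500),
      bands = band_spec("delta", 1, 4)
    )
    off <- apply(ct$values[, 1, 1, , ], 1, function(m) mean(m[upper.tri(m)]))
    mean(off[eps$labels == "pleasant"]) - mean(off[eps$labels == "unpleasant"])
  }, numeric(1))
  expect_gt(t.test(diffs)$p.value, 0.01)
})

test_that("a single ERP peak shows up at its latency in the average", {
  spec <- generator_spec(
    n_trials_per_condition = 30,
    montage = montage(c("x", "y")),
    erp_peaks = tibble::tibble(
      latency_ms = 300, width_ms = 40, amplitude = -5
    ),
    coupling = tibble::tibble(
      condition = character(), band = character(),
      chan_a = character(), chan_b = character(), kappa = numeric()
    ),
    band_sd = c(delta = 1, theta = 1, alpha = 1, beta = 1),
    noise_sd = 1, seed = 4
  )
  eps <- generate_epochs(spec)
  avg <- colMeans(eps$data[, 1, ])
  t_extremum <- epoch_times(eps)[which.min(avg)]
  expect_lt(abs(t_extremum - 300), 20)
})

test_that("artifact injection is seeded and detectable at the stated rate", {
  eps <- make_test_epochs(n_trials = 100, n_channels = 4, n_samples = 100,
    fs = 100)
  # identity at rate 0
  same <- inject_artifacts(eps, rate = 0)
  expect_identical(same$data, eps$data)
  # exactly 10 of 100 trials exceed a 150 uV max-min criterion
  bad <- inject_artifacts(eps, rate = 0.1, amplitude = 200, seed = 3)
  rej <- reject_maxmin(bad, 150)
  expect_equal(rej$rejected_trials, attr(bad, "artifact_trials"))
  expect_length(rej$rejected_trials, 10)
  # same seed -> same trials
  bad2 <- inject_artifacts(eps, rate = 0.1, amplitude = 200, seed = 3)
  expect_identical(attr(bad2, "artifact_trials"), attr(bad, "artifact_trials"))
})

test_that("default coupling encodes the planted delta effect", {
  cpl <- default_coupling()
  # delta effect: cliques of 10, 10, 5, 5 channels per condition
  n_clique_edges <- 2 * choose(10, 2) + 2 * choose(5, 2)
  dl <- cpl[cpl$band == "delta", ]
  th <- cpl[cpl$band == "theta", ]
  expect_equal(nrow(dl), 2 * n_clique_edges)
  # rho parameterization: kappa = sqrt(rho), pleasant 1.0 vs unpleasant 0.4
  expect_equal(
    sort(unique(dl$kappa[dl$condition == "pleasant"])), 1
  )
  expect_equal(
    sort(unique(dl$kappa[dl$condition == "unpleasant"])), sqrt(0.4)
  )
  # condition-independent diffuse theta synchrony over all 30 channels
  expect_equal(nrow(th), 2 * choose(30, 2))
  expect_equal(unique(th$kappa), sqrt(0.7))
  expect_identical(
    th[th$condition == "pleasant", c("chan_a", "chan_b", "kappa")],
    th[th$condition == "unpleasant", c("chan_a", "chan_b", "kappa")]
  )
  # gap = 0 makes the two conditions' tables identical
  cpl0 <- default_coupling(gap = 0)
  a <- cpl0[cpl0$condition == "pleasant", c("band", "chan_a", "chan_b", "kappa")]
  b <- cpl0[cpl0$condition == "unpleasant", c("band", "chan_a", "chan_b", "kappa")]
  expect_identical(
    dplyr::arrange(a, band, chan_a, chan_b),
    dplyr::arrange(b, band, chan_a, chan_b)
  )
  expect_error(default_coupling(gap = 0.9, base = 0.4))
})
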