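test_that("scale grid has floor(log2 N) - 1 scales below Nyquist", {
  g <- scale_grid(256, fs = 250)
  expect_equal(nrow(g), 7)
  expect_equal(nrow(scale_grid(100, fs = 250)), 5)
  g8 <- scale_grid(8, fs = 250)
  expect_equal(nrow(g8), 2)
  expect_lte(max(g8$center_freq), 250 / 2)
  expect_true(all(diff(g$center_freq) < 0))
  expect_error(scale_grid(4, fs = 100), "at least 8")
})

test_that("CWT peaks at the scale matching a sinusoid's frequency", {
  fs <- 250
  x <- sin(2 * pi * 10 * seq(0, 2 - 1 / fs, by = 1 / fs))
  w <- morlet_cwt(x, fs = fs)
  fr <- attr(w, "center_freq")
  power <- rowMeans(abs(w)^2)
  f_peak <- fr[which.max(power)]
  # within one geometric scale step of 10 Hz
  step <- max(fr[-1] / fr[-length(fr)], fr[-length(fr)] / fr[-1])
  expect_lt(max(f_peak / 10, 10 / f_peak), step)
})

test_that("CWT is linear and maps zero to zero", {
  fs <- 100
  x <- rnorm(128)
  w1 <- morlet_cwt(x, fs = fs)
  w2 <- morlet_cwt(2 * x, fs = fs)
  expect_all_equal(abs(w2), 2 * abs(w1), tol = 1e-9)
  expect_equal(max(abs(morlet_cwt(rep(0, 128), fs = fs))), 0)
})

test_that("FFT-based CWT matches naive time-domain convolution", {
  fs <- 64
  n <- 256
  tt <- (seq_len(n) - 1) / fs
  # signal concentrated mid-segment so circular wrap-around is negligible
  x <- sin(2 * pi * 10 * tt) * exp(-(tt - 2)^2 / (2 * 0.4^2))
  grid <- scale_grid(n, fs)
  keep <- which(grid$center_freq >= 4) # wavelet support short vs segment
  w_pkg <- morlet_cwt(x, fs = fs, scales = grid)
  w_naive <- oracle_morlet_cwt(x, fs, grid$scale[keep])
  central <- 64:192
  for (i in seq_along(keep)) {
    a <- w_pkg[keep[i], central]
    b <- sqrt(fs) * w_naive[i, central] # package uses per-sample scaling
    expect_lt(max(abs(a - b)) / max(abs(a)), 0.02)
  }
})

test_that("smoothed spectra are non-negative, Hermitian and smoothing works", {
  fs <- 100
  x <- rnorm(200)
  y <- rnorm(200)
  wx <- morlet_cwt(x, fs = fs)
  wy <- morlet_cwt(y, fs = fs)
  Sxx <- smoothed_spectrum(wx, cycles = 3)
  expect_true(all(Sxx >= 0))
  expect_equal(attr(Sxx, "kind"), "auto")
  Sxy <- smoothed_spectrum(wx, wy, cycles = 3)
  Syx <- smoothed_spectrum(wy, wx, cycles = 3)
  expect_all_equal(Sxy, Conj(Syx), tol = 1e-9)
  # more smoothing cycles -> smaller variance of W_xx across time
  v3 <- v6 <- 0
  for (sd in 1:30) {
    withr::with_seed(sd, z <- rnorm(200))
    wz <- morlet_cwt(z, fs = fs)
    v3 <- v3 + mean(apply(smoothed_spectrum(wz, cycles = 3), 1, var))
    v6 <- v6 + mean(apply(smoothed_spectrum(wz, cycles = 6), 1, var))
  }
  expect_lt(v6, v3)
  expect_error(smoothed_spectrum(wx, morlet_cwt(rnorm(100), fs = fs)),
    "identical scale grids")
})

test_that("wavelet coherence identities hold", {
  fs <- 100
  x <- rnorm(256)
  wx <- morlet_cwt(x, fs = fs)
  Sxx <- smoothed_spectrum(wx)
  # self-coherence and sign-flip coherence are exactly 1
  coh_self <- wavelet_coherence(smoothed_spectrum(wx, wx), Sxx, Sxx)
  expect_all_equal(coh_self, matrix(1, nrow(coh_self), ncol(coh_self)), 1e-9)
  wneg <- morlet_cwt(-x, fs = fs)
  Snn <- smoothed_spectrum(wneg)
  coh_neg <- wavelet_coherence(smoothed_spectrum(wx, wneg), Sxx, Snn)
  expect_all_equal(coh_neg, matrix(1, nrow(coh_neg), ncol(coh_neg)), 1e-9)
  # general pair: bounded in [0, 1]
  wy <- morlet_cwt(rnorm(256), fs = fs)
  coh <- wavelet_coherence(smoothed_spectrum(wx, wy), Sxx, smoothed_spectrum(wy))
  expect_gte(min(coh), 0)
  expect_lte(max(coh), 1)
})

test_that("white-noise coherence bias shrinks with the smoothing dof", {
  # smoothing over delta = c / f seconds leaves ~ n / (c * fs / f)
  # independent stretches per scale, so the spurious-coherence floor grows
  # as the center frequency falls; the fastest scales must sit well below 1
  fs <- 100
  n <- 256
  per_scale <- vapply(1:30, function(sd) {
    withr::with_seed(sd, {
      x <- rnorm(n)
      y <- rnorm(n)
    })
    wx <- morlet_cwt(x, fs = fs)
    wy <- morlet_cwt(y, fs = fs)
    coh <- wavelet_coherence(
      smoothed_spectrum(wx, wy, cycles = 3),
      smoothed_spectrum(wx, cycles = 3), smoothed_spectrum(wy, cycles = 3)
    )
    rowMeans(coh)
  }, numeric(nrow(scale_grid(n, fs))))
  m <- rowMeans(per_scale) # scales ordered fast -> slow
  expect_true(all(m > 0 & m < 1))
  # scales whose smoothing window fits the signal stay clearly below 1 ...
  fr <- scale_grid(n, fs)$center_freq
  halfw <- floor(round(3 * fs / fr) / 2)
  valid <- 2 * halfw + 1 <= n
  expect_true(all(m[valid] < 0.9))
  # ... while a scale whose window exceeds it is pure smoothing bias,
  # which is why such scales are excluded from band averaging
  expect_true(any(!valid) && all(m[!valid] > 0.95))
  expect_gt(m[length(m)], m[1]) # bias grows as the dof shrink
  # stable across realizations at the fastest scale
  expect_lt(max(abs(per_scale[1, ] - m[1])), 0.1)
})

test_that("planted delta coupling raises the coupled pair's coherence", {
  diffs <- vapply(1:30, function(sd) {
    spec <- generator_spec(
      n_trials_per_condition = 1,
      montage = montage(c("a", "b", "c", "d")),
      erp_peaks = tibble::tibble(
        latency_ms = numeric(), width_ms = numeric(), amplitude = numeric()
      ),
      coupling = tibble::tibble(
        condition = rep(c("X", "Y"), each = 1), band = "delta",
        chan_a = "a", chan_b = "b", kappa = c(0.9, 0)
      ),
      band_sd = c(delta = 5), conditions = c("X", "Y"), seed = sd
    )
    eps <- generate_epochs(spec)
    co <- band_component_coherence(
      eps, component_window("P300", 250, 500), band_spec("delta", 1, 4)
    )
    co[1, "a", "b"] - co[2, "a", "b"] # coupled trial minus uncoupled trial
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_lt(t.test(diffs, alternative = "greater")$p.value, 0.01)
})

test_that("band_scale_indices reports bands without scales by name", {
  expect_error(
    band_scale_indices(c(40, 20, 10), band_spec("delta", 1, 4)),
    "delta"
  )
  idx <- band_scale_indices(
    c(40, 20, 10, 5, 2),
    dplyr::bind_rows(band_spec("alpha", 8, 13), band_spec("delta", 1, 4))
  )
  expect_equal(idx, list(3L, 5L))
})

test_that("coherence tensor is symmetric with unit diagonal and persists", {
  eps <- make_test_epochs(n_trials = 4, n_channels = 3, n_samples = 256,
    fs = 128)
  ct <- coherence_tensor(eps,
    windows = component_window("P300", 250, 500),
    bands = band_spec("beta", 13, 30)
  )
  expect_equal(dim(ct$values), c(4, 1, 1, 3, 3))
  for (tr in 1:4) {
    m <- ct$values[tr, 1, 1, , ]
    expect_all_equal(m, t(m), 1e-12)
    expect_equal(diag(m), rep(1, 3))
    expect_true(all(m >= 0 & m <= 1))
  }
  # amplitude invariance: rescaling all channels leaves coherence unchanged
  eps2 <- eps
  eps2$data <- eps2$data * 3.7
  ct2 <- coherence_tensor(eps2,
    windows = component_window("P300", 250, 500),
    bands = band_spec("beta", 13, 30)
  )
  expect_all_equal(ct$values, ct2$values, 1e-9)
  # round trip
  path <- file.path(withr::local_tempdir(), "ct")
  write_coherence_tensor(ct, path)
  back <- read_coherence_tensor(path)
  expect_equal(back$values, ct$values)
  expect_equal(back$bands, ct$bands)
  expect_equal(back$labels, ct$labels)
  # long view
  tb <- tibble::as_tibble(ct)
  expect_equal(nrow(tb), 4 * 3) # 4 trials x 3 channel pairs
  expect_true(all(tb$coherence >= 0 & tb$coherence <= 1))
})
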