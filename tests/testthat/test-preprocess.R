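test_that("band-pass matches the analytic Butterworth magnitude response", {
  fs <- 250
  tt <- seq(0, 4 - 1 / fs, by = 1 / fs)
  rms <- function(x) sqrt(mean(x^2))
  for (f_sig in c(10, 20, 30)) {
    x <- sin(2 * pi * f_sig * tt)
    y <- bandpass(x, 0.1, 40, order = 6, fs = fs)
    gain_expected <- butter_mag2(f_sig, 0.1, 40, 6)
    expect_lt(abs(rms(y) / rms(x) - gain_expected), 0.05)
  }
  # passband flatness at 10 Hz
  x10 <- sin(2 * pi * 10 * tt)
  expect_lt(abs(rms(bandpass(x10, fs = fs)) / rms(x10) - 1), 0.05)
  # 50 Hz stopband: analytic |H|^2 = 1/(1 + (50/40)^12) ~ 0.064 at order 6;
  # the response follows the oracle and drops below 5% at order >= 8
  x50 <- sin(2 * pi * 50 * tt)
  r6 <- rms(bandpass(x50, fs = fs)) / rms(x50)
  expect_lt(abs(r6 - butter_mag2(50, 0.1, 40, 6)), 0.02)
  expect_lt(r6, 0.1)
  # order 8: interior attenuation (edges keep a finite-window transient)
  r8 <- rms(bandpass(x50, 0.1, 40, order = 8, fs = fs)[201:800]) / rms(x50)
  expect_lt(r8, 0.05)
})

test_that("band-pass removes DC exactly and is zero-phase", {
  fs <- 250
  x <- rep(7, 1000)
  expect_lt(abs(mean(bandpass(x, fs = fs))), 1e-6 * 7)
  # zero-phase: a band-passed pulse stays symmetric about its center
  pulse <- exp(-(seq_len(1000) - 500)^2 / (2 * 20^2))
  y <- bandpass(pulse, 0.1, 40, fs = fs)
  expect_equal(which.max(y), 500, tolerance = 1)
  # residual asymmetry comes only from the finite symmetric padding
  expect_lt(max(abs(y[450:550] - rev(y[450:550]))), 1e-5)
})

test_that("notch attenuates 50 Hz and leaves 10 Hz untouched", {
  fs <- 250
  tt <- seq(0, 4 - 1 / fs, by = 1 / fs)
  rms <- function(x) sqrt(mean(x^2))
  x50 <- sin(2 * pi * 50 * tt)
  y50 <- notch(x50, 50, fs = fs)
  # steady-state interior: the tone is essentially removed; the edges keep
  # an unavoidable transient of length ~ 1 / bandwidth = q / f0 seconds
  edge <- 2 * ceiling(30 / 50 * fs)
  interior <- (edge + 1):(length(x50) - edge)
  expect_lt(rms(y50[interior]) / rms(x50), 0.02)
  expect_lt(max(abs(y50)), 1.5) # edge transients stay bounded
  x10 <- sin(2 * pi * 10 * tt)
  expect_lt(abs(rms(notch(x10, 50, fs = fs)) / rms(x10) - 1), 0.02)
  expect_equal(notch(rep(0, 500), 50, fs = fs), rep(0, 500))
})

test_that("epoching slices continuous data at event samples", {
  fs <- 250
  x <- matrix(rnorm(2 * 5000), ncol = 2) # 20 s x 2 channels
  eps <- epoch_continuous(x,
    events = c(1000, 2000, 3000), pre = 200,
    post = 1000, fs = fs, labels = c("a", "b", "a"),
    montage = montage(c("c1", "c2"))
  )
  expect_equal(dim(eps), c(3, 2, 300))
  expect_equal(eps$t0, -200)
  # duration 1200 ms at 250 Hz = 300 samples; sample alignment:
  expect_equal(eps$data[2, 1, ], x[(2000 - 50):(2000 + 249), 1])
  # event too close to the edge is skipped with a warning
  expect_warning(
    eps2 <- epoch_continuous(x,
      events = c(10, 2000), pre = 200, post = 1000,
      fs = fs, labels = c("a", "b"), montage = montage(c("c1", "c2"))
    ),
    "skip"
  )
  expect_equal(dim(eps2)[1], 1)
  # 10 samples at 100 Hz
  eps3 <- epoch_continuous(matrix(rnorm(1000), ncol = 1),
    events = c(500, 600),
    pre = 0, post = 100, fs = 100, labels = c("a", "b"),
    montage = montage("c1")
  )
  expect_equal(dim(eps3)[3], 10)
})

test_that("baseline correction zeroes the pre-stimulus mean and is idempotent", {
  eps <- make_test_epochs(n_trials = 4, n_channels = 3, n_samples = 100,
    fs = 100)
  eps$data <- eps$data + 100 # constant offset
  bc <- baseline_correct(eps)
  pre <- epoch_times(eps) < 0
  for (tr in 1:4) {
    for (ch in 1:3) {
      expect_lt(abs(mean(bc$data[tr, ch, pre])), 1e-10)
    }
  }
  # constant channel becomes all-zero
  eps$data[1, 2, ] <- 100
  expect_equal(max(abs(baseline_correct(eps)$data[1, 2, ])), 0)
  # idempotent
  expect_equal(baseline_correct(bc)$data, bc$data)
})

test_that("max-min rejection uses a strict threshold", {
  eps <- make_test_epochs(n_trials = 3, n_channels = 2, n_samples = 50,
    fs = 100)
  eps$data[] <- 0
  eps$data[1, 1, 1] <- 160 # span 160 > 150 -> rejected
  eps$data[2, 1, 1] <- 10 # span 10 -> kept
  eps$data[3, 2, 1] <- 150 # span exactly 150 -> kept (strict)
  rej <- reject_maxmin(eps, 150)
  expect_equal(rej$rejected_trials, 1L)
  expect_s3_class(rej, "rejection_report")
})

test_that("low-variance channel rejection follows the documented rule", {
  eps <- make_test_epochs(n_trials = 20, n_channels = 3, n_samples = 50,
    fs = 100)
  eps$data[1:4, 2, ] <- 0 # channel 2 flat in 20% of trials -> removed
  rej <- reject_low_variance_channels(eps, 0.5, 0.10)
  expect_equal(rej$rejected_channels, "ch2")
  # flat in exactly 10% -> kept (strict "more than")
  eps2 <- make_test_epochs(n_trials = 20, n_channels = 3, n_samples = 50,
    fs = 100)
  eps2$data[1:2, 2, ] <- 0
  expect_length(reject_low_variance_channels(eps2, 0.5, 0.10)$rejected_channels, 0)
  # all channels lively -> none removed
  expect_length(
    reject_low_variance_channels(make_test_epochs())$rejected_channels, 0
  )
})

test_that("high-variance epoch rejection flags outlier trials", {
  eps <- make_test_epochs(n_trials = 50, n_channels = 5, n_samples = 80,
    fs = 100)
  eps$data[7, , ] <- eps$data[7, , ] * 10 # outlier on all channels
  rej <- reject_high_variance_epochs(eps, channel_fraction = 0.2, z_cut = 3)
  expect_equal(rej$rejected_trials, 7L)
  # homogeneous epochs -> none rejected
  expect_length(
    reject_high_variance_epochs(make_test_epochs(n_trials = 30))$rejected_trials,
    0
  )
  # excessive in exactly 20% of channels -> kept (strict "more than")
  eps2 <- make_test_epochs(n_trials = 50, n_channels = 5, n_samples = 80,
    fs = 100)
  eps2$data[7, 1, ] <- eps2$data[7, 1, ] * 10 # 1 of 5 channels = 20%
  expect_false(7L %in%
    reject_high_variance_epochs(eps2, channel_fraction = 0.2)$rejected_trials)
})

test_that("apply_rejection drops flagged trials and channels together", {
  eps <- make_test_epochs(n_trials = 10, n_channels = 4, n_samples = 50,
    fs = 100)
  eps$data[3, , 1] <- eps$data[3, , 1] + 500 # spike -> maxmin span > 150
  eps$data[, 2, ] <- 0
  rej_t <- reject_maxmin(eps, 150)
  rej_c <- reject_low_variance_channels(eps)
  kept <- apply_rejection(eps, rej_t, rej_c)
  expect_equal(dim(kept), c(9, 3, 50))
  expect_false("ch2" %in% kept$montage$channel_names)
  expect_equal(kept$labels, eps$labels[-3])
})

test_that("rejection reports serialize to JSON", {
  eps <- make_test_epochs()
  eps$data[2, , 1] <- eps$data[2, , 1] + 500 # spike -> maxmin span > 150
  rej <- reject_maxmin(eps, 150)
  path <- withr::local_tempfile(fileext = ".json")
  write_rejection_json(list(rej), path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed[[1]]$rule, "maxmin")
  expect_equal(unlist(parsed[[1]]$rejected_trials), 2)
})
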