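# Zero-phase filtering. The band-pass applies the squared Butterworth
# magnitude response in the frequency domain (the ideal forward-backward
# filter, with exactly zero phase); a coefficient-form IIR realization of a
# 0.1 Hz edge at typical EEG rates is numerically ill-conditioned, while the
# frequency-domain form is exact and stable. Signals are symmetrically
# mirror-padded before the FFT to suppress circular wrap-around.

# |H(f)|^2 of an order-n Butterworth band-pass applied forward + backward
butter_mag2 <- function(f, f_low, f_high, order) {
  h <- rep(1, length(f))
  if (!is.null(f_high) && is.finite(f_high)) {
    h <- h / (1 + (f / f_high)^(2 * order))
  }
  if (!is.null(f_low) && f_low > 0) {
    hp <- ifelse(f > 0, 1 / (1 + (f_low / pmax(f, 1e-300))^(2 * order)), 0)
    h <- h * hp
  }
  h
}

mirror_pad_length <- function(n, fs, f_low) {
  # long enough for the slowest edge's transient to settle inside the pad
  target <- if (!is.null(f_low) && f_low > 0) ceiling(3 * fs / f_low) else 64L
  as.integer(max(32, target))
}

# indices of the even (symmetric, period 2n - 2) extension covering
# positions 1 - np .. n + np of a length-n signal
symmetric_ext_index <- function(n, np) {
  q <- seq.int(1L - np, n + np)
  if (n == 1) {
    return(rep(1L, length(q)))
  }
  p <- 2L * n - 2L
  r <- (q - 1L) %% p
  as.integer(ifelse(r < n, r + 1L, 2L * n - 1L - r))
}

# smallest 5-smooth integer >= m with the same parity as n (so the
# extra padding splits evenly between the two sides)
smooth_fft_size <- function(m, n) {
  repeat {
    k <- m
    for (f in c(2, 3, 5)) while (k %% f == 0) k <- k / f
    if (k == 1 && (m - n) %% 2 == 0) {
      return(as.integer(m))
    }
    m <- m + 1
  }
}

# x: samples x series matrix
zp_filter_mat <- function(x, fs, gain_fun) {
  n <- nrow(x)
  np <- mirror_pad_length(n, fs, attr(gain_fun, "f_low"))
  m <- smooth_fft_size(n + 2L * np, n)
  np <- (m - n) %/% 2L
  xp <- x[symmetric_ext_index(n, np), , drop = FALSE]
  f <- fs * c(0:(floor(m / 2)), -((ceiling(m / 2) - 1):1)) / m
  g <- gain_fun(abs(f))
  out <- x
  # chunk the columns to bound the complex FFT workspace
  chunk <- max(1L, 256L)
  for (start in seq(1L, ncol(x), by = chunk)) {
    cols <- start:min(ncol(x), start + chunk - 1L)
    y <- Re(mvfft(mvfft(xp[, cols, drop = FALSE]) * g, inverse = TRUE)) / m
    out[, cols] <- y[(np + 1):(np + n), , drop = FALSE]
  }
  out
}

apply_zp <- function(x, fs, gain_fun) {
  if (inherits(x, "epoch_set")) {
    d <- dim(x$data)
    flat <- matrix(aperm(x$data, c(3, 1, 2)), nrow = d[3])
    out <- zp_filter_mat(flat, fs = x$fs, gain_fun)
    x$data <- aperm(array(out, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
    dimnames(x$data) <- list(NULL, x$montage$channel_names, NULL)
    x
  } else if (is.matrix(x)) {
    zp_filter_mat(x, fs, gain_fun)
  } else {
    drop(zp_filter_mat(matrix(as.numeric(x), ncol = 1), fs, gain_fun))
  }
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies the magnitude-squared response of an order-`order` Butterworth
#' band-pass (the forward-backward, zero-phase filter) in the frequency
#' domain after mirror padding. The default 0.1--40 Hz, order 6 matches the
#' acquisition passband of the reference recordings. With `f_low > 0` the DC
#' component of the output is (numerically) zero.
#'
#' @param x Numeric vector, a samples x series matrix, or an [epoch_set()]
#'   (filtered per trial and channel).
#' @param f_low,f_high Band edges in Hz; `f_low = 0` gives a pure low-pass,
#'   `f_high = Inf` a pure high-pass.
#' @param order Butterworth order of each (forward) pass.
#' @param fs Sampling rate in Hz; taken from `x` when it is an epoch set.
#' @return Filtered object of the same shape/class as `x`.
#' @export
#' @examples
#' t <- seq(0, 2, by = 1 / 250)
#' x <- sin(2 * pi * 10 * t) + sin(2 * pi * 50 * t)
#' y <- bandpass(x, 0.1, 40, fs = 250)
bandpass <- function(x, f_low = 0.1, f_high = 40, order = 6, fs = NULL) {
  if (inherits(x, "epoch_set")) fs <- x$fs
  if (is.null(fs)) abort("fs is required unless x is an epoch_set")
  nyq <- fs / 2
  if (is.finite(f_high) && f_high >= nyq) {
    abort(sprintf("f_high = %g Hz is not below the Nyquist frequency %g Hz", f_high, nyq))
  }
  if (f_low >= ifelse(is.finite(f_high), f_high, nyq)) {
    abort("f_low must be below f_high")
  }
  gain <- function(f) butter_mag2(f, f_low, f_high, order)
  attr(gain, "f_low") <- f_low
  apply_zp(x, fs, gain)
}

#' Zero-phase notch filter
#'
#' Applies the squared magnitude response of a second-order constrained
#' biquad notch (quality factor `q`) in the frequency domain after
#' symmetric mirror padding — the ideal forward-backward, exactly
#' zero-phase notch — for line-noise removal.
#'
#' @inheritParams bandpass
#' @param f0 Notch center frequency, Hz (default 50, European mains).
#' @param q Quality factor; bandwidth is roughly `f0 / q` Hz.
#' @return Filtered object of the same shape/class as `x`.
#' @export
notch <- function(x, f0 = 50, q = 30, fs = NULL) {
  if (inherits(x, "epoch_set")) fs <- x$fs
  if (is.null(fs)) abort("fs is required unless x is an epoch_set")
  if (f0 >= fs / 2) {
    abort(sprintf("notch frequency %g Hz must be below the Nyquist frequency %g Hz", f0, fs / 2))
  }
  w0 <- 2 * pi * f0 / fs
  al <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + al)
  a <- c(1, -2 * cos(w0) / (1 + al), (1 - al) / (1 + al))
  gain <- function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    Mod((b[1] + b[2] * z + b[3] * z^2) / (a[1] + a[2] * z + a[3] * z^2))^2
  }
  # pad length scales with the notch bandwidth f0 / q (transient length)
  attr(gain, "f_low") <- f0 / q
  apply_zp(x, fs, gain)
}
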