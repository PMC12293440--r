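#' Scale grid for the Morlet continuous wavelet transform
#'
#' The number of scales is `floor(log2(N)) - 1` for an input of `N` samples.
#' Center frequencies are logarithmically spaced between a low end limited
#' by the signal length (at least two full cycles of the center frequency
#' within the segment, `f_min = 2 * fs / N`) and a high end limited by the
#' Nyquist frequency (the wavelet's spectral support kept below Nyquist,
#' `f_max = (fs / 2) * omega0 / (omega0 + 2)`). Frequencies are returned in
#' decreasing order of scale, i.e. `center_freq[1]` is the highest.
#'
#' @param N Number of samples (>= 8).
#' @param fs Sampling rate, Hz.
#' @param omega0 Morlet center-frequency parameter (default 6).
#' @return A tibble with columns `scale` (seconds) and `center_freq` (Hz),
#'   frequencies strictly decreasing.
#' @export
#' @examples
#' scale_grid(256, fs = 250)
scale_grid <- function(N, fs, omega0 = 6) {
  if (N < 8) abort("at least 8 samples are required to build a scale grid")
  n_sc <- floor(log2(N)) - 1
  f_max <- (fs / 2) * omega0 / (omega0 + 2)
  f_min <- 2 * fs / N
  if (f_min >= f_max) f_min <- f_max / 2^(n_sc - 1)
  freqs <- exp(seq(log(f_max), log(f_min), length.out = n_sc))
  tibble::tibble(scale = omega0 / (2 * pi * freqs), center_freq = freqs)
}

#' Morlet continuous wavelet transform
#'
#' Complex analytic CWT with the Morlet prototype
#' `pi^(-1/4) exp(i omega0 t) exp(-t^2 / 2)`, computed in the frequency
#' domain with L2 (unit-energy) scale normalization. The transform is linear
#' in its input: scaling the signal scales the coefficient magnitudes by the
#' same factor.
#'
#' @param x Numeric vector (one channel) or samples x channels matrix.
#' @param fs Sampling rate, Hz.
#' @param scales Optional tibble from [scale_grid()]; computed from the
#'   signal length by default.
#' @param omega0 Morlet parameter.
#' @return For vector input, a complex scales x samples matrix of class
#'   `cwt_coefficients` with attributes `center_freq`, `fs`; for matrix
#'   input, a complex samples x channels x scales array with the same
#'   attributes.
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 1, by = 1 / 250))
#' w <- morlet_cwt(x, fs = 250)
morlet_cwt <- function(x, fs, scales = NULL, omega0 = 6) {
  vec_in <- !is.matrix(x)
  X <- if (vec_in) matrix(as.numeric(x), ncol = 1) else x
  n <- nrow(X)
  if (n < 8) abort("morlet_cwt() needs at least 8 samples")
  if (is.null(scales)) scales <- scale_grid(n, fs, omega0)
  if (nrow(scales) == 0) abort("empty scale grid")
  omega <- 2 * pi * fs * c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / n
  Fx <- mvfft(X)
  out <- array(0i, dim = c(n, ncol(X), nrow(scales)))
  for (k in seq_len(nrow(scales))) {
    s <- scales$scale[k]
    psi <- ifelse(omega > 0,
      pi^(-1 / 4) * sqrt(2 * pi * s * fs) * exp(-(s * omega - omega0)^2 / 2),
      0
    )
    out[, , k] <- mvfft(Fx * psi, inverse = TRUE) / n
  }
  attr(out, "center_freq") <- scales$center_freq
  attr(out, "fs") <- fs
  attr(out, "omega0") <- omega0
  if (vec_in) {
    m <- t(out[, 1, ])
    attributes(m) <- c(attributes(m), list(
      center_freq = scales$center_freq, fs = fs, omega0 = omega0
    ))
    class(m) <- c("cwt_coefficients", class(m))
    m
  } else {
    class(out) <- c("cwt_array", class(out))
    out
  }
}

cwt_grid_matches <- function(a, b) {
  isTRUE(all.equal(attr(a, "center_freq"), attr(b, "center_freq"))) &&
    identical(dim(a), dim(b)) && identical(attr(a, "fs"), attr(b, "fs"))
}

#' Time-smoothed wavelet auto-/cross-spectrum
#'
#' At each time `t` and scale of center frequency `f`, integrates
#' `S_a(tau, f) * Conj(S_b(tau, f))` over the window
#' `[t - delta/2, t + delta/2]` with `delta = cycles / f` seconds, truncated
#' at the segment edges. With `a == b` the result is real and non-negative
#' (returned as such); otherwise it is the complex cross-spectrum and
#' satisfies `W_ab = Conj(W_ba)`.
#'
#' @param a,b `cwt_coefficients` from [morlet_cwt()] on the same grid.
#' @param cycles Number of integration cycles `c` in the smoothing window.
#' @return A scales x samples matrix (real for the auto case, complex
#'   otherwise) with attribute `kind` either `"auto"` or `"cross"`.
#' @export
smoothed_spectrum <- function(a, b = a, cycles = 3) {
  if (!cwt_grid_matches(a, b)) {
    abort("smoothed_spectrum() needs coefficients on identical scale grids")
  }
  if (cycles <= 0) abort("cycles must be positive")
  fs <- attr(a, "fs")
  freqs <- attr(a, "center_freq")
  n <- ncol(a)
  auto <- identical(a, b)
  prod <- unclass(a) * Conj(unclass(b))
  out <- matrix(if (auto) 0 else 0i, nrow = nrow(a), ncol = n)
  dt <- 1 / fs
  for (k in seq_len(nrow(a))) {
    h <- floor(round(cycles / freqs[k] * fs) / 2)
    cs <- cumsum(prod[k, ])
    lo <- pmax(1, seq_len(n) - h)
    hi <- pmin(n, seq_len(n) + h)
    v <- (cs[hi] - c(0i, cs)[lo]) * dt
    out[k, ] <- if (auto) pmax(Re(v), 0) else v
  }
  attr(out, "center_freq") <- freqs
  attr(out, "fs") <- fs
  attr(out, "kind") <- if (auto) "auto" else "cross"
  out
}

#' Wavelet coherence from smoothed spectra
#'
#' The normalized wavelet cross-spectrum
#' `|W_xy| / sqrt(W_xx * W_yy)`, clipped to \[0, 1\]. Points where either
#' auto-spectrum vanishes are set to 0; their count is returned in the
#' `n_zero` attribute with a warning.
#'
#' @param Wxy Complex cross-spectrum from [smoothed_spectrum()].
#' @param Wxx,Wyy Real auto-spectra on the same grid.
#' @return A real scales x samples matrix of coherence values in \[0, 1\].
#' @export
wavelet_coherence <- function(Wxy, Wxx, Wyy) {
  stopifnot(
    identical(dim(Wxy), dim(Wxx)),
    identical(dim(Wxy), dim(Wyy))
  )
  denom <- Re(Wxx) * Re(Wyy)
  bad <- denom <= 0
  coh <- matrix(0, nrow = nrow(Wxy), ncol = ncol(Wxy))
  coh[!bad] <- abs(Wxy[!bad]) / sqrt(denom[!bad])
  coh <- pmin(coh, 1)
  if (any(bad)) {
    warn(sprintf(
      "%d time-scale point(s) had a zero auto-spectrum; coherence set to 0",
      sum(bad)
    ))
  }
  attr(coh, "n_zero") <- sum(bad)
  attr(coh, "center_freq") <- attr(Wxy, "center_freq")
  coh
}

band_scale_indices <- function(freqs, bands) {
  lapply(seq_len(nrow(bands)), function(i) {
    idx <- which(freqs >= bands$f_low[i] & freqs <= bands$f_high[i])
    if (length(idx) == 0) {
      abort(sprintf(
        "no CWT scale falls inside band %s (%g-%g Hz); grid: %s Hz",
        bands$band[i], bands$f_low[i], bands$f_high[i],
        paste(signif(freqs, 3), collapse = ", ")
      ))
    }
    idx
  })
}

#' Band- and window-averaged coherence matrix for one component/band
#'
#' For every trial and channel pair: the CWT is computed on the full epoch
#' (reducing edge artifacts relative to transforming the cut window), the
#' smoothed coherence is averaged over the window's time samples and over
#' the scales whose center frequency lies inside the band, and the result is
#' stored as a symmetric channel x channel matrix with unit diagonal. Scales
#' whose full time-smoothing window exceeds the epoch length are excluded
#' from band averaging (their coherence is dominated by smoothing bias);
#' a band must retain at least one valid scale.
#'
#' @param epochs An [epoch_set()].
#' @param window One-row tibble from [component_window()].
#' @param band One-row tibble from [band_spec()].
#' @param cycles Smoothing cycles `c`.
#' @param omega0 Morlet parameter.
#' @return Array trials x channels x channels of coherence values in \[0, 1\].
#' @export
band_component_coherence <- function(epochs, window, band, cycles = 3,
                                     omega0 = 6) {
  ct <- coherence_tensor(
    epochs,
    windows = window, bands = band,
    cycles = cycles, omega0 = omega0
  )
  out <- ct$values[, 1, 1, , , drop = FALSE]
  dim(out) <- dim(ct$values)[c(1, 4, 5)]
  dimnames(out) <- list(
    NULL, epochs$montage$channel_names,
    epochs$montage$channel_names
  )
  out
}

#' Per-trial coherence tensor over all components and bands
#'
#' Runs the Morlet CWT once per trial and channel on the full epoch, then
#' aggregates smoothed wavelet coherence into one symmetric channel x
#' channel matrix per (trial, component, band). A scale only contributes to
#' a band when its full smoothing window (`2 * floor(c * fs / f / 2) + 1`
#' samples) fits inside the epoch; slower scales are excluded, and a band
#' with no remaining valid scale is an error.
#'
#' @param epochs An [epoch_set()].
#' @param windows Component windows tibble (default [default_windows()]).
#' @param bands Band tibble (default [default_bands()]).
#' @param cycles Smoothing cycles `c` (`delta = c / f` seconds).
#' @param omega0 Morlet parameter.
#' @return An object of class `coherence_tensor`: a list with `values`
#'   (array trial x component x band x channel x channel), `montage`,
#'   `labels`, and the analysis parameters.
#' @export
coherence_tensor <- function(epochs, windows = default_windows(),
                             bands = default_bands(), cycles = 3,
                             omega0 = 6) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  n <- d[3]
  grid <- scale_grid(n, epochs$fs, omega0)
  freqs <- grid$center_freq
  nyq_bad <- bands$f_high > epochs$fs / 2
  if (any(nyq_bad)) {
    abort(sprintf(
      "band %s exceeds the Nyquist frequency",
      paste(bands$band[nyq_bad], collapse = ", ")
    ))
  }
  bidx <- band_scale_indices(freqs, bands)
  wins <- t(vapply(seq_len(nrow(windows)), function(i) {
    w <- window_to_samples(windows[i, ], epochs$fs, epochs$t0, n_samples = n)
    c(w[["start"]], w[["end"]] - 1L) # 0-based inclusive for the C++ side
  }, integer(2)))
  halfw <- as.integer(floor(round(cycles / freqs * epochs$fs) / 2))
  # scale-validity rule: a scale only enters band averaging when its full
  # smoothing window (2 * halfw + 1 samples) fits inside the epoch; slower
  # scales would be pure smoothing bias (coherence ~ 1 regardless of signal)
  valid <- (2L * halfw + 1L) <= n
  bidx <- lapply(seq_along(bidx), function(i) {
    keep <- bidx[[i]][valid[bidx[[i]]]]
    if (length(keep) == 0) {
      abort(sprintf(
        paste(
          "no scale in band %s has a smoothing window that fits the epoch",
          "(%d samples); valid center frequencies: %s Hz"
        ),
        bands$band[i], n,
        paste(signif(freqs[valid], 3), collapse = ", ")
      ))
    }
    keep
  })

  vals <- array(0, dim = c(d[1], nrow(windows), nrow(bands), d[2], d[2]))
  zero_total <- 0
  for (tr in seq_len(d[1])) {
    S <- morlet_cwt(t(epochs$data[tr, , ]), epochs$fs,
      scales = grid, omega0 = omega0
    )
    res <- coh_aggregate_cpp(
      unclass(S), wins,
      lapply(bidx, function(i) as.integer(i - 1L)), halfw
    )
    vals[tr, , , , ] <- aperm(res$coh, c(3, 4, 1, 2))
    zero_total <- zero_total + res$zero_count
  }
  if (zero_total > 0) {
    warn(sprintf(
      "%d time-scale point(s) with zero auto-spectrum set to 0 coherence",
      zero_total
    ))
  }
  structure(
    list(
      values = vals, montage = epochs$montage, labels = epochs$labels,
      components = windows$component, bands = bands$band,
      windows = windows, band_table = bands,
      fs = epochs$fs, cycles = cycles, omega0 = omega0,
      center_freq = freqs, subject_id = epochs$subject_id
    ),
    class = "coherence_tensor"
  )
}

#' @export
print.coherence_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<coherence_tensor> %d trials x %d components x %d bands x %d channels\n",
    d[1], d[2], d[3], d[4]
  ))
  cat(
    "  components:", paste(x$components, collapse = ", "),
    "| bands:", paste(x$bands, collapse = ", "), "\n"
  )
  invisible(x)
}

#' Coherence tensor as a long tibble of channel pairs
#'
#' @param x A `coherence_tensor`.
#' @param ... Unused.
#' @return Tibble with columns `trial`, `label`, `component`, `band`,
#'   `chan_a`, `chan_b`, `coherence` (upper-triangle pairs only).
#' @export
as_tibble.coherence_tensor <- function(x, ...) {
  ch <- x$montage$channel_names
  C <- length(ch)
  pairs <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)
  d <- dim(x$values)
  purrr::map_dfr(seq_len(d[2]), function(k) {
    purrr::map_dfr(seq_len(d[3]), function(b) {
      m <- x$values[, k, b, , , drop = FALSE]
      dim(m) <- c(d[1], C, C)
      tibble::tibble(
        trial = rep(seq_len(d[1]), times = nrow(pairs)),
        label = rep(x$labels, times = nrow(pairs)),
        component = x$components[k], band = x$bands[b],
        chan_a = rep(ch[pairs[, 1]], each = d[1]),
        chan_b = rep(ch[pairs[, 2]], each = d[1]),
        coherence = unlist(lapply(seq_len(nrow(pairs)), function(p) {
          m[, pairs[p, 1], pairs[p, 2]]
        }))
      )
    })
  })
}

#' Persist / load a coherence tensor
#'
#' The values are stored as a named-dimension array in RDS form next to a
#' JSON sidecar carrying the montage, bands, windows, smoothing parameters
#' and package version.
#'
#' @param ct A `coherence_tensor`.
#' @param path Base path; `.rds` and `.json` extensions are appended.
#' @return `write_coherence_tensor()` returns `path` invisibly;
#'   `read_coherence_tensor()` the restored `coherence_tensor`.
#' @export
write_coherence_tensor <- function(ct, path) {
  vals <- ct$values
  dimnames(vals) <- list(
    NULL, ct$components, ct$bands,
    ct$montage$channel_names, ct$montage$channel_names
  )
  saveRDS(vals, paste0(path, ".rds"))
  sidecar <- list(
    channels = ct$montage$channel_names,
    components = ct$components, bands = ct$bands,
    windows = ct$windows, band_table = ct$band_table,
    labels = ct$labels, fs = ct$fs, cycles = ct$cycles,
    omega0 = ct$omega0, center_freq = ct$center_freq,
    subject_id = ct$subject_id,
    package_version = as.character(packageVersion("cohnet"))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_coherence_tensor
#' @export
read_coherence_tensor <- function(path) {
  vals <- readRDS(paste0(path, ".rds"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dimnames(vals) <- NULL
  structure(
    list(
      values = vals, montage = montage(side$channels),
      labels = side$labels, components = side$components,
      bands = side$bands,
      windows = tibble::as_tibble(side$windows),
      band_table = tibble::as_tibble(side$band_table),
      fs = side$fs, cycles = side$cycles, omega0 = side$omega0,
      center_freq = side$center_freq, subject_id = side$subject_id
    ),
    class = "coherence_tensor"
  )
}
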