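#' Frequency band specification
#'
#' @param name Band name (conventionally one of delta, theta, alpha, beta).
#' @param f_low,f_high Band edges in Hz, `0 < f_low < f_high`.
#' @return A one-row tibble with columns `band`, `f_low`, `f_high`.
#' @export
#' @examples
#' band_spec("alpha", 8, 13)
band_spec <- function(name, f_low, f_high) {
  if (!(f_low > 0 && f_low < f_high)) {
    abort("band edges must satisfy 0 < f_low < f_high")
  }
  tibble::tibble(band = as.character(name), f_low = f_low, f_high = f_high)
}

#' Default clinical band partition
#'
#' Delta 1--4, theta 4--8, alpha 8--13, beta 13--30 Hz: the standard clinical
#' partition, consistent with a 0.1--40 Hz acquisition passband. The analysis
#' never relies on these exact edges; any non-overlapping partition below the
#' Nyquist frequency can be supplied instead.
#'
#' @return A tibble with one row per band.
#' @export
#' @examples
#' default_bands()
default_bands <- function() {
  dplyr::bind_rows(
    band_spec("delta", 1, 4),
    band_spec("theta", 4, 8),
    band_spec("alpha", 8, 13),
    band_spec("beta", 13, 30)
  )
}

#' ERP component time window
#'
#' @param name Component name (N100, N200 or P300 by convention).
#' @param t_start,t_end Window bounds in ms post-stimulus,
#'   `0 <= t_start < t_end`.
#' @return A one-row tibble with columns `component`, `t_start`, `t_end`.
#' @export
#' @examples
#' component_window("P300", 250, 500)
component_window <- function(name, t_start, t_end) {
  if (!(t_start >= 0 && t_start < t_end)) {
    abort("component window must satisfy 0 <= t_start < t_end")
  }
  tibble::tibble(
    component = as.character(name),
    t_start = t_start, t_end = t_end
  )
}

#' Default ERP component windows
#'
#' N100 70--140 ms, N200 150--250 ms, P300 250--500 ms: conventional widths
#' around the canonical component latencies.
#'
#' @return A tibble with one row per component.
#' @export
default_windows <- function() {
  dplyr::bind_rows(
    component_window("N100", 70, 140),
    component_window("N200", 150, 250),
    component_window("P300", 250, 500)
  )
}

#' Convert a component window to a sample-index range
#'
#' Epoch time is ms relative to stimulus onset; sample `i` (0-based) sits at
#' `t0 + i * 1000 / fs` ms. The returned range is half-open `[start, end)` in
#' 0-based indices: `start` is the first sample at time >= `t_start`, `end`
#' the first at time >= `t_end`.
#'
#' @param window One-row tibble from [component_window()] (or a list with
#'   `component`, `t_start`, `t_end`).
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first epoch sample relative to the stimulus, in ms
#'   (negative for pre-stimulus baselines).
#' @param n_samples Epoch length in samples; when given, the window is
#'   validated against the epoch span.
#' @return Integer vector `c(start, end)`, 0-based half-open.
#' @export
#' @examples
#' window_to_samples(component_window("N100", 0, 100), fs = 250, t0 = -200)
window_to_samples <- function(window, fs, t0, n_samples = NULL) {
  start <- as.integer(ceiling((window$t_start - t0) * fs / 1000 - 1e-9))
  end <- as.integer(ceiling((window$t_end - t0) * fs / 1000 - 1e-9))
  if (!is.null(n_samples)) {
    span_end <- t0 + (n_samples - 1) * 1000 / fs
    if (window$t_start < t0 || window$t_end > span_end + 1000 / fs) {
      abort(sprintf(
        "window %s [%g, %g] ms lies outside the epoch span [%g, %g] ms",
        window$component, window$t_start, window$t_end, t0, span_end
      ))
    }
    end <- min(end, as.integer(n_samples))
  }
  if (end - start < 8) {
    abort(sprintf(
      "window %s [%g, %g] ms covers %d samples at %g Hz; at least 8 required",
      window$component, window$t_start, window$t_end, end - start, fs
    ))
  }
  c(start = start, end = end)
}
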