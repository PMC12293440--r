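#' Labeled single-trial epochs
#'
#' The central container of the pipeline: a trials x channels x samples
#' amplitude array in microvolts, with sampling rate, epoch timing, binary
#' condition labels and a [montage()]. All trials share `fs`, `t0` and the
#' number of samples; the channel dimension follows the montage order.
#'
#' @param data Numeric array, trials x channels x samples (microvolts).
#' @param fs Sampling rate, Hz.
#' @param t0 Time of the first sample relative to the stimulus, ms.
#' @param labels Per-trial condition tags; at most two distinct values.
#' @param montage A [montage()] whose length matches `dim(data)[2]`.
#' @param subject_id Free-text subject identifier.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, t0, labels, montage, subject_id = "synthetic") {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (dim(data)[2] != length(montage)) {
    abort(sprintf(
      "data has %d channels but montage has %d",
      dim(data)[2], length(montage)
    ))
  }
  labels <- as.character(labels)
  if (length(labels) != dim(data)[1]) {
    abort("one label per trial required")
  }
  if (length(unique(labels)) > 2) {
    abort("epoch_set labels must take at most two distinct values")
  }
  if (fs <= 0) abort("fs must be positive")
  dimnames(data) <- list(NULL, montage$channel_names, NULL)
  structure(
    list(
      data = data, fs = fs, t0 = t0, labels = labels,
      montage = montage, subject_id = subject_id
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> subject %s: %d trials x %d channels x %d samples @ %g Hz\n",
    x$subject_id, d[1], d[2], d[3], x$fs
  ))
  cat(sprintf(
    "  time %g..%g ms, labels: %s\n",
    x$t0, x$t0 + (d[3] - 1) * 1000 / x$fs,
    paste(sprintf("%s (%d)", names(table(x$labels)), table(x$labels)),
      collapse = ", "
    )
  ))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' Epoch sample times in ms relative to stimulus onset
#' @param epochs An [epoch_set()].
#' @return Numeric vector of length `dim(epochs)[3]`.
#' @export
epoch_times <- function(epochs) {
  epochs$t0 + (seq_len(dim(epochs$data)[3]) - 1) * 1000 / epochs$fs
}

#' Subset an epoch set by trial and/or channel
#'
#' @param epochs An [epoch_set()].
#' @param trials Integer or logical trial index (default: all).
#' @param channels Integer/logical index or channel labels (default: all).
#' @return A new [epoch_set()].
#' @export
subset_epochs <- function(epochs, trials = NULL, channels = NULL) {
  d <- dim(epochs$data)
  if (is.null(trials)) trials <- seq_len(d[1])
  if (is.null(channels)) channels <- seq_len(d[2])
  if (is.character(channels)) {
    channels <- match(channels, epochs$montage$channel_names)
    if (anyNA(channels)) abort("unknown channel label in subset")
  }
  keep_names <- epochs$montage$channel_names[channels]
  pos <- epochs$montage$positions
  epoch_set(
    data = epochs$data[trials, channels, , drop = FALSE],
    fs = epochs$fs, t0 = epochs$t0,
    labels = epochs$labels[trials],
    montage = montage(keep_names, if (!is.null(pos)) pos[channels, , drop = FALSE]),
    subject_id = epochs$subject_id
  )
}

#' Epoch amplitudes as a long tibble
#'
#' @param x An [epoch_set()].
#' @param ... Unused.
#' @return A tibble with columns `trial`, `label`, `channel`, `time_ms`,
#'   `amplitude`.
#' @export
as_tibble.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  tms <- epoch_times(x)
  tibble::tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    label = rep(x$labels, times = d[2] * d[3]),
    channel = rep(rep(x$montage$channel_names, each = d[1]), times = d[3]),
    time_ms = rep(tms, each = d[1] * d[2]),
    amplitude = as.vector(x$data)
  )
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
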