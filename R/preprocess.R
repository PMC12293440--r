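#' Cut a continuous recording into stimulus-locked epochs
#'
#' Each epoch starts `pre` ms before its event sample and ends `post` ms
#' after it, for a total of `round((pre + post) / 1000 * fs)` samples with
#' `t0 = -pre`. Events whose margins fall outside the recording are skipped
#' with a warning and counted in the `n_skipped` attribute.
#'
#' @param x Continuous data, samples x channels matrix (microvolts), or the
#'   list returned by [read_raw()].
#' @param events Integer sample indices (1-based) of stimulus onsets.
#' @param pre,post Epoch margins in ms before/after the stimulus.
#' @param fs Sampling rate, Hz (taken from `x` when it carries one).
#' @param labels Optional per-event condition tags.
#' @param montage Optional [montage()]; defaults to the one carried by `x`
#'   or generic channel names.
#' @param subject_id Subject identifier.
#' @return An [epoch_set()]; attribute `n_skipped` counts dropped events.
#' @export
epoch_continuous <- function(x, events, pre = 200, post = 1000, fs = NULL,
                             labels = NULL, montage = NULL,
                             subject_id = "unknown") {
  if (is.list(x) && !is.data.frame(x)) {
    if (is.null(fs)) fs <- x$fs
    if (is.null(montage)) montage <- x$montage
    x <- x$data
  }
  if (is.null(fs)) abort("fs is required")
  x <- as.matrix(x)
  if (is.null(montage)) {
    montage <- montage(paste0("ch", seq_len(ncol(x))))
  }
  n_pre <- round(pre / 1000 * fs)
  n_len <- round((pre + post) / 1000 * fs)
  starts <- events - n_pre
  ok <- starts >= 1 & (starts + n_len - 1) <= nrow(x)
  if (any(!ok)) {
    warn(sprintf(
      "%d event(s) too close to the recording edge were skipped", sum(!ok)
    ))
  }
  starts <- starts[ok]
  if (!is.null(labels)) labels <- labels[ok]
  if (length(starts) == 0) abort("no event fits inside the recording")
  dat <- array(0, dim = c(length(starts), ncol(x), n_len))
  for (i in seq_along(starts)) {
    dat[i, , ] <- t(x[starts[i]:(starts[i] + n_len - 1), , drop = FALSE])
  }
  if (is.null(labels)) labels <- rep("unlabeled", length(starts))
  out <- epoch_set(dat,
    fs = fs, t0 = -pre, labels = labels,
    montage = montage, subject_id = subject_id
  )
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window (default: everything strictly before the stimulus), making that
#' mean exactly zero. The operation is idempotent.
#'
#' @param epochs An [epoch_set()].
#' @param window Length-2 numeric, baseline bounds in ms, as the half-open
#'   interval `[start, end)` — so the default `c(t0, 0)` excludes the
#'   stimulus-onset sample.
#' @return The corrected [epoch_set()].
#' @export
baseline_correct <- function(epochs, window = NULL) {
  tms <- epoch_times(epochs)
  if (is.null(window)) window <- c(epochs$t0, 0)
  sel <- tms >= window[1] & tms < window[2]
  if (!any(sel)) {
    abort(sprintf(
      "baseline window [%g, %g] ms lies outside the epoch span [%g, %g] ms",
      window[1], window[2], min(tms), max(tms)
    ))
  }
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl) # recycles over samples
  epochs
}

rejection_report <- function(rule, rejected_trials = integer(),
                             rejected_channels = character(),
                             thresholds = list()) {
  structure(
    list(
      rule = rule,
      rejected_trials = as.integer(sort(unique(rejected_trials))),
      rejected_channels = as.character(rejected_channels),
      thresholds = thresholds
    ),
    class = "rejection_report"
  )
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf(
    "<rejection_report> rule %s: %d trial(s), %d channel(s) rejected\n",
    x$rule, length(x$rejected_trials), length(x$rejected_channels)
  ))
  invisible(x)
}

#' Max-min amplitude artifact rejection
#'
#' A trial is rejected when the difference between its highest and lowest
#' amplitude strictly exceeds `range_threshold` in at least one of the
#' examined channels. The default 150 microvolt criterion targets eye
#' movements; restricting `channels` to EOG or frontal leads with a 100
#' microvolt threshold gives the ocular variant of the rule.
#'
#' @param epochs An [epoch_set()].
#' @param range_threshold Peak-to-peak threshold in microvolts.
#' @param channels Channel labels (or indices) the rule examines;
#'   default all.
#' @return A `rejection_report`.
#' @export
reject_maxmin <- function(epochs, range_threshold = 150, channels = NULL) {
  stopifnot(range_threshold > 0)
  d <- epochs$data
  if (!is.null(channels)) {
    if (is.character(channels)) {
      channels <- match(channels, epochs$montage$channel_names)
      if (anyNA(channels)) abort("unknown channel label in reject_maxmin()")
    }
    d <- d[, channels, , drop = FALSE]
  }
  span <- apply(d, c(1, 2), function(v) max(v) - min(v))
  bad <- which(apply(span, 1, max) > range_threshold)
  rejection_report("maxmin",
    rejected_trials = bad,
    thresholds = list(range_threshold = range_threshold)
  )
}

#' Flat-channel rejection
#'
#' A channel is removed when its per-trial variance falls below
#' `var_threshold` in strictly more than `trial_fraction` of the trials
#' (defaults: 0.5 microvolt^2 in more than 10% of trials).
#'
#' @param epochs An [epoch_set()].
#' @param var_threshold Variance floor, microvolts^2.
#' @param trial_fraction Tolerated fraction of low-variance trials.
#' @return A `rejection_report` listing channels to remove.
#' @export
reject_low_variance_channels <- function(epochs, var_threshold = 0.5,
                                         trial_fraction = 0.10) {
  stopifnot(var_threshold > 0, trial_fraction > 0)
  v <- apply(epochs$data, c(1, 2), var) # trials x channels
  frac_low <- colMeans(v < var_threshold)
  bad <- which(frac_low > trial_fraction)
  if (length(bad) == dim(epochs$data)[2]) {
    abort("all channels fall below the variance floor; pipeline cannot proceed")
  }
  rejection_report("low_variance_channel",
    rejected_channels = epochs$montage$channel_names[bad],
    thresholds = list(
      var_threshold = var_threshold,
      trial_fraction = trial_fraction
    )
  )
}

#' High-variance (muscle artifact) epoch rejection
#'
#' "Excessive" variance is operationalized per channel as a z-score of the
#' trial's variance across trials exceeding `z_cut`; an epoch is rejected
#' when strictly more than `channel_fraction` of its channels are excessive.
#'
#' @param epochs An [epoch_set()] with at least 3 trials.
#' @param channel_fraction Tolerated fraction of excessive channels.
#' @param z_cut Variance z-score defining "excessive".
#' @return A `rejection_report`.
#' @export
reject_high_variance_epochs <- function(epochs, channel_fraction = 0.20,
                                        z_cut = 3) {
  stopifnot(channel_fraction > 0, channel_fraction < 1)
  if (dim(epochs$data)[1] < 3) {
    abort("variance z-scores need at least 3 trials")
  }
  v <- apply(epochs$data, c(1, 2), var) # trials x channels
  mu <- colMeans(v)
  s <- apply(v, 2, sd)
  s[s == 0] <- Inf # a constant-variance channel is never "excessive"
  z <- sweep(sweep(v, 2, mu), 2, s, "/")
  frac_exc <- rowMeans(z > z_cut)
  bad <- which(frac_exc > channel_fraction)
  rejection_report("high_variance_epoch",
    rejected_trials = bad,
    thresholds = list(channel_fraction = channel_fraction, z_cut = z_cut)
  )
}

#' Apply rejection reports to an epoch set
#'
#' Drops every trial and channel named by the given reports. Rules are pure
#' predicates of the input, so the result does not depend on the order in
#' which reports were computed.
#'
#' @param epochs An [epoch_set()].
#' @param ... One or more `rejection_report` objects.
#' @return The reduced [epoch_set()].
#' @export
apply_rejection <- function(epochs, ...) {
  reports <- list(...)
  drop_trials <- sort(unique(unlist(lapply(reports, `[[`, "rejected_trials"))))
  drop_channels <- unique(unlist(lapply(reports, `[[`, "rejected_channels")))
  d <- dim(epochs$data)
  keep_t <- setdiff(seq_len(d[1]), drop_trials)
  keep_c <- setdiff(epochs$montage$channel_names, drop_channels)
  if (length(keep_t) == 0) abort("all trials rejected")
  if (length(keep_c) == 0) abort("all channels rejected")
  subset_epochs(epochs, trials = keep_t, channels = keep_c)
}

#' Serialize rejection reports to JSON
#'
#' @param reports A list of `rejection_report` objects (or a single one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rejection_json <- function(reports, path) {
  if (inherits(reports, "rejection_report")) reports <- list(reports)
  jsonlite::write_json(
    lapply(reports, function(r) {
      list(
        rule = r$rule, rejected_trials = r$rejected_trials,
        rejected_channels = r$rejected_channels, thresholds = r$thresholds
      )
    }),
    path,
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
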