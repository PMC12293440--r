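#' Coupling table for the epoch generator
#'
#' Describes the planted, condition-dependent band-limited coupling: each row
#' gives one channel pair, the band it is coupled in, the condition, and the
#' mixing coefficient kappa in \[0, 1\]. Channels connected by coupling rows
#' (within one condition and band) share a common narrowband source with
#' weight kappa and keep an independent residual with weight sqrt(1 - kappa^2),
#' so the expected inter-channel correlation of the band component is kappa^2.
#'
#' `default_coupling()` is parameterized by the target inter-channel source
#' correlation `rho` (so the row weight is `kappa = sqrt(rho)`). It plants the
#' condition effect in the delta band over four regional cliques of the
#' 30-channel montage (two 10-channel fronto-central/centro-parietal blocks
#' and two 5-channel temporo-parietal/occipital blocks): rho = `base + gap`
#' in the first condition and `base` in the second. On top of that it adds a
#' condition-independent diffuse theta-band synchrony over all channels
#' (`rho = theta_rho` in both conditions), mimicking widespread
#' low-frequency background coupling such as thalamocortical drive or volume
#' conduction. With `gap = 0` the two conditions are identically distributed.
#'
#' @param conditions Length-2 character vector of condition names.
#' @param gap Between-condition source-correlation difference (default 0.6).
#' @param base Source correlation of the weakly coupled condition
#'   (default 0.4).
#' @param band Band carrying the effect (default `"delta"`).
#' @param channels Channel labels carved into the coupled cliques; defaults
#'   to the standard 30-channel montage.
#' @param theta_rho Source correlation of the condition-independent diffuse
#'   theta synchrony over all `channels` (default 0.7; 0 disables it).
#' @return A tibble with columns `condition`, `band`, `chan_a`, `chan_b`,
#'   `kappa`.
#' @export
default_coupling <- function(conditions = c("pleasant", "unpleasant"),
                             gap = 0.6, base = 0.4, band = "delta",
                             channels = standard_montage(30)$channel_names,
                             theta_rho = 0.7) {
  stopifnot(
    base >= 0, base + gap <= 1, gap >= 0,
    theta_rho >= 0, theta_rho <= 1
  )
  cliques <- coupling_cliques(channels)
  clique_rows <- function(cond, rho) {
    dplyr::bind_rows(lapply(cliques, function(g) {
      pairs <- utils::combn(g, 2)
      tibble::tibble(
        condition = cond, band = band,
        chan_a = pairs[1, ], chan_b = pairs[2, ], kappa = sqrt(rho)
      )
    }))
  }
  out <- dplyr::bind_rows(
    clique_rows(conditions[1], base + gap),
    clique_rows(conditions[2], base)
  )
  if (theta_rho > 0 && length(channels) >= 2) {
    pairs <- utils::combn(channels, 2)
    theta_rows <- lapply(conditions, function(cond) {
      tibble::tibble(
        condition = cond, band = "theta",
        chan_a = pairs[1, ], chan_b = pairs[2, ], kappa = sqrt(theta_rho)
      )
    })
    out <- dplyr::bind_rows(out, theta_rows)
  }
  out
}

# split the montage into the default coupled blocks: two 10-channel and two
# 5-channel cliques for >= 30 channels, proportionally smaller otherwise
coupling_cliques <- function(channels) {
  nc <- length(channels)
  if (nc < 4) {
    return(list(channels))
  }
  sizes <- pmax(1L, as.integer(round(nc * c(1, 1, 0.5, 0.5) / 3)))
  sizes[length(sizes)] <- sizes[length(sizes)] + (nc - sum(sizes))
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-length(ends)] + 1L)
  lapply(seq_along(sizes), function(i) channels[starts[i]:ends[i]])
}

#' Specification for the synthetic epoch generator
#'
#' Defaults emulate the emotional-protocol recordings: 30 channels at 250 Hz,
#' epochs from -200 to 1000 ms, ERP-like deflections near 100/200/300 ms,
#' per-band narrowband background activity, and a delta-band coupling effect
#' between conditions (see [default_coupling()]).
#'
#' @param n_trials_per_condition Trials per condition (>= 1).
#' @param montage A [montage()].
#' @param fs Sampling rate, Hz.
#' @param t_pre,t_post Epoch margins in ms before/after the stimulus.
#' @param erp_peaks Tibble with columns `latency_ms`, `width_ms` (Gaussian
#'   SD), `amplitude` (microvolts, signed).
#' @param coupling Coupling tibble, see [default_coupling()].
#' @param band_sd Named numeric: per-band background SD in microvolts.
#' @param noise_sd Broadband white-noise SD in microvolts (> 0).
#' @param artifact_rate Fraction of trials later given a blink-like
#'   transient by [inject_artifacts()] (stored, not applied here).
#' @param conditions Length-2 character vector of condition names.
#' @param seed Integer seed; identical specs with identical seeds generate
#'   byte-identical epoch sets.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_trials_per_condition = 200,
                           montage = standard_montage(30),
                           fs = 250, t_pre = 200, t_post = 1000,
                           erp_peaks = tibble::tibble(
                             latency_ms = c(100, 200, 300),
                             width_ms = c(15, 20, 40),
                             amplitude = c(-5, -4, 6)
                           ),
                           coupling = default_coupling(),
                           band_sd = c(delta = 5, theta = 4, alpha = 4, beta = 3),
                           noise_sd = 2,
                           artifact_rate = 0,
                           conditions = c("pleasant", "unpleasant"),
                           seed = 1L) {
  stopifnot(
    n_trials_per_condition >= 1, noise_sd > 0,
    artifact_rate >= 0, artifact_rate <= 1,
    length(conditions) == 2
  )
  if (nrow(coupling) > 0 && any(coupling$kappa < 0 | coupling$kappa > 1)) {
    abort("coupling coefficients must lie in [0, 1]")
  }
  structure(
    list(
      n_trials_per_condition = as.integer(n_trials_per_condition),
      montage = montage, fs = fs, t_pre = t_pre, t_post = t_post,
      erp_peaks = erp_peaks, coupling = coupling, band_sd = band_sd,
      noise_sd = noise_sd, artifact_rate = artifact_rate,
      conditions = as.character(conditions), seed = as.integer(seed)
    ),
    class = "generator_spec"
  )
}

#' Generate the NT/ST/DT session design
#'
#' Reproduces the cognitive-session trial mix: by default five runs of 120
#' trials, 75% Non-Target, 12.5% Shallow-Target and 12.5% Deep-Target cases.
#' Exact counts are `round(proportion * total)` with any rounding remainder
#' assigned to NT; the order is randomized by `seed` within the whole
#' session and then split into runs.
#'
#' @param n_runs Number of runs.
#' @param trials_per_run Trials in each run.
#' @param mix Named proportions summing to 1 (default
#'   `c(NT = .75, ST = .125, DT = .125)`).
#' @param trial_duration_s Nominal trial duration in seconds (metadata only).
#' @param seed Integer seed.
#' @return A tibble with columns `run`, `trial`, `case`, carrying the mix
#'   and duration as attributes.
#' @export
#' @examples
#' d <- generate_session_design(seed = 1)
#' table(d$case)
generate_session_design <- function(n_runs = 5, trials_per_run = 120,
                                    mix = c(NT = 0.75, ST = 0.125, DT = 0.125),
                                    trial_duration_s = 1.25, seed = 1L) {
  if (abs(sum(mix) - 1) > 1e-9) abort("case proportions must sum to 1")
  total <- n_runs * trials_per_run
  counts <- round(mix * total)
  leftover <- total - sum(counts)
  nt <- if ("NT" %in% names(mix)) "NT" else names(mix)[1]
  counts[nt] <- counts[nt] + leftover
  cases <- rep(names(counts), counts)
  cases <- withr::with_seed(seed, sample(cases))
  out <- tibble::tibble(
    run = rep(seq_len(n_runs), each = trials_per_run),
    trial = rep(seq_len(trials_per_run), times = n_runs),
    case = cases
  )
  attr(out, "mix") <- mix
  attr(out, "trial_duration_s") <- trial_duration_s
  out
}

# scale factor so band-filtered unit white noise has (expected) unit variance
band_gain_norm <- function(n, fs, f_low, f_high, order = 4) {
  f <- fs * c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / n
  g <- butter_mag2(abs(f), f_low, f_high, order)
  sqrt(mean(g^2))
}

# narrowband unit-variance noise, one column per series
band_noise <- function(n, n_series, fs, f_low, f_high, order = 4) {
  w <- matrix(rnorm(n * n_series), nrow = n)
  gain <- function(f) butter_mag2(f, f_low, f_high, order)
  attr(gain, "f_low") <- f_low
  zp_filter_mat(w, fs, gain) / band_gain_norm(2 * n, fs, f_low, f_high, order)
}

#' Generate two-condition single-trial epochs
#'
#' Each trial is the sum of (i) Gaussian-windowed ERP-like deflections at the
#' specified latencies, scaled per channel by a fixed topography gain, (ii)
#' per-band narrowband background noise in which coupled channel groups share
#' a common band-limited source (mixing weight kappa, independent residual
#' weight sqrt(1 - kappa^2)), and (iii) broadband white noise. Narrowband
#' components are white noise shaped by a 4th-order zero-phase band-pass.
#' Trials alternate between the two conditions; everything is deterministic
#' under the spec's seed.
#'
#' @param spec A [generator_spec()].
#' @return An [epoch_set()] with `2 * n_trials_per_condition` trials.
#' @export
#' @examples
#' eps <- generate_epochs(generator_spec(n_trials_per_condition = 4, seed = 7))
#' dim(eps)
generate_epochs <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  fs <- spec$fs
  nyq <- fs / 2
  bands <- default_bands()
  bands <- bands[bands$band %in% names(spec$band_sd), , drop = FALSE]
  used_bands <- union(bands$band, unique(spec$coupling$band))
  band_edges <- lapply(setNames(used_bands, used_bands), function(b) {
    row <- default_bands()[default_bands()$band == b, ]
    if (nrow(row) == 0) abort(sprintf("unknown band '%s' in coupling", b))
    c(row$f_low, row$f_high)
  })
  too_high <- vapply(band_edges, function(e) e[2] > nyq, logical(1))
  if (any(too_high)) {
    abort(sprintf(
      "band(s) %s exceed the Nyquist frequency %g Hz",
      paste(names(band_edges)[too_high], collapse = ", "), nyq
    ))
  }

  C <- length(spec$montage)
  n <- round((spec$t_pre + spec$t_post) / 1000 * fs)
  tms <- -spec$t_pre + (seq_len(n) - 1) * 1000 / fs
  n_trials <- 2L * spec$n_trials_per_condition
  labels <- rep(spec$conditions, times = spec$n_trials_per_condition)

  # per-(condition, band): channel -> kappa and coupling-group id
  group_of <- function(cond, band) {
    rows <- spec$coupling[
      spec$coupling$condition == cond & spec$coupling$band == band, ,
      drop = FALSE
    ]
    kappa <- rep(0, C)
    grp <- rep(NA_integer_, C)
    if (nrow(rows) > 0) {
      ia <- match(rows$chan_a, spec$montage$channel_names)
      ib <- match(rows$chan_b, spec$montage$channel_names)
      if (anyNA(ia) || anyNA(ib)) abort("coupling names channels missing from the montage")
      # union-find over coupled pairs -> connected coupling groups
      parent <- seq_len(C)
      find <- function(i) {
        while (parent[i] != i) i <- parent[i]
        i
      }
      for (r in seq_along(ia)) {
        ra <- find(ia[r])
        rb <- find(ib[r])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        kappa[ia[r]] <- max(kappa[ia[r]], rows$kappa[r])
        kappa[ib[r]] <- max(kappa[ib[r]], rows$kappa[r])
      }
      roots <- vapply(seq_len(C), find, integer(1))
      touched <- unique(c(ia, ib))
      grp[touched] <- match(roots[touched], unique(roots[touched]))
    }
    list(kappa = kappa, group = grp)
  }
  coupling_map <- lapply(setNames(spec$conditions, spec$conditions), function(cond) {
    lapply(setNames(used_bands, used_bands), function(b) group_of(cond, b))
  })

  withr::with_seed(spec$seed, {
    gains <- runif(C, 0.5, 1) # fixed ERP topography
    erp <- rep(0, n)
    for (i in seq_len(nrow(spec$erp_peaks))) {
      pk <- spec$erp_peaks[i, ]
      erp <- erp + pk$amplitude * exp(-(tms - pk$latency_ms)^2 / (2 * pk$width_ms^2))
    }
    erp_mat <- outer(erp, gains) # samples x channels

    dat <- array(0, dim = c(n_trials, C, n))
    for (tr in seq_len(n_trials)) {
      cond <- labels[tr]
      sig <- erp_mat
      for (b in used_bands) {
        cm <- coupling_map[[cond]][[b]]
        edges <- band_edges[[b]]
        sdb <- if (b %in% names(spec$band_sd)) spec$band_sd[[b]] else 0
        if (sdb <= 0 && all(cm$kappa == 0)) next
        groups <- unique(cm$group[!is.na(cm$group)])
        src <- if (length(groups) > 0) {
          band_noise(n, length(groups), fs, edges[1], edges[2])
        } else {
          NULL
        }
        res <- band_noise(n, C, fs, edges[1], edges[2])
        comp <- res
        for (g in groups) {
          idx <- which(!is.na(cm$group) & cm$group == g)
          k <- cm$kappa[idx]
          comp[, idx] <- outer(src[, match(g, groups)], k) +
            sweep(res[, idx, drop = FALSE], 2, sqrt(1 - k^2), "*")
        }
        sig <- sig + sdb * comp
      }
      sig <- sig + spec$noise_sd * matrix(rnorm(n * C), nrow = n)
      dat[tr, , ] <- t(sig)
    }
    out <- epoch_set(dat,
      fs = fs, t0 = -spec$t_pre, labels = labels,
      montage = spec$montage, subject_id = "synthetic"
    )
    if (spec$artifact_rate > 0) {
      out <- inject_artifacts(out,
        rate = spec$artifact_rate,
        amplitude = 200, seed = spec$seed + 1L
      )
    }
    out
  })
}

#' Inject blink-like low-frequency artifacts
#'
#' Adds a slow half-cosine transient of the given peak amplitude to the
#' frontal channels (labels starting with Fp/FP/AF, or the first two
#' channels when none match) of `ceiling(rate * n_trials)` randomly chosen
#' trials. Affected trial indices are recorded in the `artifact_trials`
#' attribute of the result.
#'
#' @param epochs An [epoch_set()].
#' @param rate Fraction of trials to corrupt, in \[0, 1\].
#' @param amplitude Peak amplitude of the transient, microvolts.
#' @param seed Integer seed choosing the trials.
#' @return The corrupted [epoch_set()].
#' @export
inject_artifacts <- function(epochs, rate, amplitude = 200, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) {
    attr(epochs, "artifact_trials") <- integer()
    return(epochs)
  }
  d <- dim(epochs$data)
  n_bad <- ceiling(rate * d[1])
  frontal <- grep("^(Fp|FP|AF)", epochs$montage$channel_names)
  if (length(frontal) == 0) frontal <- seq_len(min(2, d[2]))
  tms <- epoch_times(epochs)
  center <- tms[round(length(tms) / 2)]
  half_ms <- 200
  bump <- ifelse(abs(tms - center) <= half_ms,
    amplitude * cos(pi * (tms - center) / (2 * half_ms))^2, 0
  )
  bad <- withr::with_seed(seed, sample(d[1], n_bad))
  for (tr in bad) {
    for (ch in frontal) {
      epochs$data[tr, ch, ] <- epochs$data[tr, ch, ] + bump
    }
  }
  attr(epochs, "artifact_trials") <- sort(bad)
  epochs
}
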