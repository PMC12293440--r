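#' Plot the trial-average ERP waveform
#'
#' Channel-average (or per-channel) mean waveform per condition.
#'
#' @param object An [epoch_set()].
#' @param channels Optional channel labels to include (default: all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epoch_set <- function(object, channels = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(channels)) df <- dplyr::filter(df, .data$channel %in% channels)
  df <- df |>
    dplyr::group_by(.data$label, .data$channel, .data$time_ms) |>
    dplyr::summarise(amplitude = mean(.data$amplitude), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time_ms, y = .data$amplitude,
    group = interaction(.data$channel, .data$label),
    colour = .data$label
  )) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "time (ms)", y = "amplitude (\u00b5V)",
      colour = "condition", title = "Trial-average waveforms"
    ) +
    ggplot2::theme_minimal()
}

#' Plot condition-mean coherence matrices
#'
#' Trial-averaged connectivity per condition for one component and band,
#' plus their difference.
#'
#' @param object A [coherence_tensor()].
#' @param component,band Names selecting the slice (defaults: first each).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coherence_tensor <- function(object, component = NULL, band = NULL,
                                      ...) {
  if (is.null(component)) component <- object$components[1]
  if (is.null(band)) band <- object$bands[1]
  df <- as_tibble(object) |>
    dplyr::filter(.data$component == !!component, .data$band == !!band) |>
    dplyr::group_by(.data$label, .data$chan_a, .data$chan_b) |>
    dplyr::summarise(coherence = mean(.data$coherence), .groups = "drop")
  ch <- object$montage$channel_names
  df$chan_a <- factor(df$chan_a, levels = ch)
  df$chan_b <- factor(df$chan_b, levels = ch)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$chan_a, y = .data$chan_b,
    fill = .data$coherence
  )) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~label) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("Mean wavelet coherence: %s, %s band", component, band)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6),
      axis.text.y = ggplot2::element_text(size = 6)
    )
}

#' Plot per-repeat classification metrics
#'
#' @param object An `eval_report` from [repeated_cv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_repeat, -"repeat_id",
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(
      x = NULL, y = "%",
      title = sprintf(
        "%s + %s: %d-fold CV x %d repeats",
        object$selector, object$classifier,
        object$cv_folds, object$cv_repeats
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot the top-ranked features
#'
#' @param object A `feature_ranking` from [ttest_rank()], [relieff_rank()]
#'   or [mrmr_rank()].
#' @param n_top Number of features to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_ranking <- function(object, n_top = 20, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$rank) |>
    head(n_top)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = sprintf("%s score", attr(object, "method")), y = NULL,
      title = sprintf("Top %d features", nrow(df))
    ) +
    ggplot2::theme_minimal()
}
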