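metric_set_vec <- function(ms) {
  c(
    as.numeric(ms$strength), as.numeric(ms$clustering),
    ms$energy, ms$global_efficiency, ms$transitivity, ms$char_path_length
  )
}

#' Assemble per-trial feature vectors from graph metric sets
#'
#' Concatenates, per trial and in combo order, the block
#' `[strength(1..C), clustering(1..C), energy, efficiency, transitivity,
#' path_length]` of each requested component, yielding
#' `|combo| * (2 * C + 4)` features: 64 per component for a 30-channel
#' montage, 128 for 62 channels. Feature names follow the stable scheme
#' `component__metric__channel` (`component__metric` for the four global
#' metrics); the band lives in the `band` column.
#'
#' @param metric_tbl Tibble with columns `trial`, `component`, and a
#'   list-column `metric_set` of `graph_metric_set` objects (one row per
#'   trial x component), e.g. z-scored sets from [surrogate_zscore()].
#' @param combo Character vector of component names to concatenate.
#' @param band Band name used in the feature names.
#' @param labels Optional per-trial labels (in trial order).
#' @return A tibble with columns `trial`, `label`, `band` and one column per
#'   feature.
#' @export
assemble_features <- function(metric_tbl, combo, band, labels = NULL) {
  if (length(combo) == 0) abort("combo must name at least one component")
  missing <- setdiff(combo, unique(metric_tbl$component))
  if (length(missing) > 0) {
    abort(paste("missing component(s):", paste(missing, collapse = ", ")))
  }
  trials <- sort(unique(metric_tbl$trial))
  blocks <- lapply(combo, function(comp) {
    rows <- metric_tbl[metric_tbl$component == comp, ]
    rows <- rows[match(trials, rows$trial), ]
    if (anyNA(rows$trial)) {
      abort(sprintf("component %s misses some trials", comp))
    }
    m <- do.call(rbind, lapply(rows$metric_set, metric_set_vec))
    ch <- names(rows$metric_set[[1]]$strength)
    if (is.null(ch)) ch <- paste0("ch", seq_len((ncol(m) - 4) / 2))
    colnames(m) <- c(
      paste(comp, "strength", ch, sep = "__"),
      paste(comp, "clustering", ch, sep = "__"),
      paste(comp, c(
        "energy", "efficiency", "transitivity",
        "path_length"
      ), sep = "__")
    )
    m
  })
  feat <- do.call(cbind, blocks)
  if (is.null(labels)) labels <- rep(NA_character_, length(trials))
  dplyr::bind_cols(
    tibble::tibble(trial = trials, label = labels, band = band),
    tibble::as_tibble(feat)
  )
}

feature_columns <- function(features) {
  setdiff(names(features), c("trial", "label", "band"))
}

#' Write / read a feature table as CSV
#'
#' One row per trial, header = feature names, with `trial`, `band` and the
#' final `label` column.
#'
#' @param features Feature tibble from [graph_features()] or
#'   [assemble_features()].
#' @param path Output file.
#' @return `write_feature_csv()` returns `path` invisibly;
#'   `read_feature_csv()` the restored tibble.
#' @export
write_feature_csv <- function(features, path) {
  cols <- c("trial", "band", feature_columns(features), "label")
  write.csv(features[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- tibble::as_tibble(read.csv(path, check.names = FALSE))
  df[, c("trial", "label", "band", setdiff(names(df), c("trial", "label", "band")))]
}
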