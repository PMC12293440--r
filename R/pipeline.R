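#' Run the full analysis pipeline
#'
#' Orchestrates generate/load -> preprocess -> wavelet coherence -> graph
#' features -> classification, and writes every stage's outputs plus a run
#' manifest to `out_dir`. Rerunning with the same configuration and seed
#' reproduces identical outputs.
#'
#' @param config A [pipeline_config()] or the path to a YAML configuration
#'   (see [write_config_template()]).
#' @param epochs An [epoch_set()]; `NULL` generates synthetic data from
#'   `generator` with the config's seed.
#' @param generator Optional [generator_spec()] used when `epochs` is
#'   `NULL`.
#' @param out_dir Output directory (`NULL` skips writing).
#' @param preprocess Apply band-pass/baseline/artifact rejection before the
#'   coherence stage (default `TRUE`).
#' @param bands_to_classify Bands evaluated by the classifier stage
#'   (default: all configured bands).
#' @return A list with `reports` (named per-band `eval_report`s),
#'   `features` (tibble), `rejections`, `manifest`.
#' @export
run_pipeline <- function(config, epochs = NULL, generator = NULL,
                         out_dir = NULL, preprocess = TRUE,
                         bands_to_classify = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  timings <- list()
  warnings_log <- character()
  note <- function(w) warnings_log <<- c(warnings_log, conditionMessage(w))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- withCallingHandlers(expr, warning = function(w) {
      note(w)
      invokeRestart("muffleWarning")
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    message(sprintf("[%s] done in %.1fs", name, timings[[name]]))
    res
  }

  input_digest <- NULL
  if (is.null(epochs)) {
    if (is.null(generator)) {
      generator <- generator_spec(seed = config$seed)
    }
    epochs <- stage("simulate", generate_epochs(generator))
  }
  validate_config(config, epochs)

  rejections <- list()
  if (preprocess) {
    pre <- stage("preprocess", {
      eps <- bandpass(epochs)
      eps <- baseline_correct(eps)
      rej_amp <- reject_maxmin(eps, 150)
      rej_var <- reject_high_variance_epochs(eps)
      rej_chan <- reject_low_variance_channels(eps)
      list(
        epochs = apply_rejection(eps, rej_amp, rej_var, rej_chan),
        rejections = list(rej_amp, rej_var, rej_chan)
      )
    })
    epochs <- pre$epochs
    rejections <- pre$rejections
    message(sprintf(
      "[preprocess] kept %d trials, %d channels (%d trial(s) rejected)",
      dim(epochs$data)[1], dim(epochs$data)[2],
      length(unique(unlist(lapply(rejections, `[[`, "rejected_trials"))))
    ))
  }

  ct <- stage("coherence", coherence_tensor(
    epochs,
    windows = config$windows, bands = config$bands,
    cycles = config$cycles, omega0 = config$omega0
  ))

  features <- stage("graph_features", graph_features(
    ct,
    component_combo = config$component_combo,
    sparsity = config$sparsity, n_surrogates = config$n_surrogates,
    seed = config$seed
  ))

  if (is.null(bands_to_classify)) bands_to_classify <- config$bands$band
  reports <- stage("classify", {
    setNames(
      lapply(bands_to_classify, function(b) {
        repeated_cv(
          dplyr::filter(features, .data$band == b),
          selector = config$selector, classifier = config$classifier,
          n_top_features = config$n_top_features,
          cv_folds = config$cv_folds, cv_repeats = config$cv_repeats,
          seed = config$seed, positive_class = config$positive_class
        )
      }),
      bands_to_classify
    )
  })

  manifest <- list(
    config = unclass_config(config),
    package_version = as.character(packageVersion("cohnet")),
    seed = config$seed,
    n_trials = dim(epochs$data)[1], n_channels = dim(epochs$data)[2],
    input_digest = input_digest,
    timings = timings,
    warnings = warnings_log,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_csv(features, file.path(out_dir, "features.csv"))
    for (b in names(reports)) {
      write_eval_report(reports[[b]], file.path(out_dir, paste0("eval_", b)))
    }
    if (length(rejections) > 0) {
      write_rejection_json(rejections, file.path(out_dir, "rejections.json"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  list(
    reports = reports, features = features, rejections = rejections,
    manifest = manifest, coherence = ct
  )
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$bands <- as.data.frame(out$bands)
  out$windows <- as.data.frame(out$windows)
  out
}
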