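#' Pipeline configuration
#'
#' Bundles every tunable of the analysis: band partition, ERP component
#' windows, which components feed the feature vector, graph sparsity,
#' surrogate count, feature selector and classifier, and the cross-validation
#' layout. Defaults: sparsity 0.3 (upper end of the usual 0.1--0.3 sweep),
#' 100 surrogate graphs, ReliefF top-20 features, RBF-kernel SVM, 10-fold
#' cross-validation.
#'
#' @param bands Tibble of band definitions, see [default_bands()].
#' @param windows Tibble of component windows, see [default_windows()].
#' @param component_combo Character subset of `windows$component` whose
#'   features are concatenated (default: all three components).
#' @param sparsity Proportion of strongest edges kept by proportional
#'   thresholding, in (0, 1]; the reference sweep uses 0.1--0.3.
#' @param n_surrogates Surrogate graphs per connectivity matrix.
#' @param n_top_features Features kept after ranking.
#' @param selector One of `"relieff"`, `"ttest"`, `"mrmr"`.
#' @param classifier One of `"svm_rbf"`, `"lda"`, `"knn"`.
#' @param cv_folds,cv_repeats Cross-validation folds and repeats.
#' @param cycles Integration cycles `c` of the coherence smoothing window
#'   (`delta = c / f` seconds at frequency `f`).
#' @param omega0 Morlet center-frequency parameter.
#' @param positive_class Label treated as "positive" for sensitivity; `NULL`
#'   picks `pleasant`/`DT` when present, else the last label in sort order.
#' @param seed Integer seed governing every random stage.
#' @return An object of class `pipeline_config`.
#' @export
#' @examples
#' pipeline_config(sparsity = 0.3, selector = "ttest")
pipeline_config <- function(bands = default_bands(),
                            windows = default_windows(),
                            component_combo = windows$component,
                            sparsity = 0.3,
                            n_surrogates = 100,
                            n_top_features = 20,
                            selector = c("relieff", "ttest", "mrmr"),
                            classifier = c("svm_rbf", "lda", "knn"),
                            cv_folds = 10,
                            cv_repeats = 100,
                            cycles = 3,
                            omega0 = 6,
                            positive_class = NULL,
                            seed = 1L) {
  cfg <- list(
    bands = bands, windows = windows,
    component_combo = as.character(component_combo),
    sparsity = sparsity, n_surrogates = as.integer(n_surrogates),
    n_top_features = as.integer(n_top_features),
    selector = match.arg(selector), classifier = match.arg(classifier),
    cv_folds = as.integer(cv_folds), cv_repeats = as.integer(cv_repeats),
    cycles = cycles, omega0 = omega0,
    positive_class = positive_class, seed = as.integer(seed)
  )
  problems <- config_problems(cfg)
  if (length(problems) > 0) {
    abort(paste0(
      "invalid pipeline configuration:\n",
      paste("-", problems, collapse = "\n")
    ))
  }
  structure(cfg, class = "pipeline_config")
}

config_problems <- function(cfg, epochs = NULL) {
  p <- character()
  if (!(cfg$sparsity > 0 && cfg$sparsity <= 1)) {
    p <- c(p, "sparsity must lie in (0, 1]")
  }
  if (cfg$n_surrogates < 1) p <- c(p, "n_surrogates must be >= 1")
  if (cfg$n_top_features < 1) p <- c(p, "n_top_features must be >= 1")
  if (cfg$cv_folds < 2) p <- c(p, "cv_folds must be >= 2")
  if (cfg$cv_repeats < 1) p <- c(p, "cv_repeats must be >= 1")
  if (cfg$cycles <= 0) p <- c(p, "cycles must be positive")
  if (length(cfg$component_combo) == 0) {
    p <- c(p, "component_combo must name at least one component")
  }
  missing <- setdiff(cfg$component_combo, cfg$windows$component)
  if (length(missing) > 0) {
    p <- c(p, paste(
      "component_combo names unknown components:",
      paste(missing, collapse = ", ")
    ))
  }
  for (i in seq_len(nrow(cfg$bands))) {
    b <- cfg$bands[i, ]
    if (!(b$f_low > 0 && b$f_low < b$f_high)) {
      p <- c(p, sprintf("band %s has invalid edges", b$band))
    }
  }
  if (!is.null(epochs)) {
    nyq <- epochs$fs / 2
    bad <- cfg$bands$f_high > nyq
    if (any(bad)) {
      p <- c(p, sprintf(
        "band %s upper edge %g Hz exceeds the Nyquist frequency %g Hz",
        cfg$bands$band[bad], cfg$bands$f_high[bad], nyq
      ))
    }
    n <- dim(epochs$data)[3]
    span_end <- epochs$t0 + (n - 1) * 1000 / epochs$fs
    for (i in seq_len(nrow(cfg$windows))) {
      w <- cfg$windows[i, ]
      if (w$t_start < epochs$t0 || w$t_end > span_end + 1000 / epochs$fs) {
        p <- c(p, sprintf(
          "window %s [%g, %g] ms outside the epoch span [%g, %g] ms",
          w$component, w$t_start, w$t_end, epochs$t0, span_end
        ))
      }
    }
  }
  p
}

#' Validate a configuration against an epoch set
#'
#' Checks that all bands lie below the Nyquist frequency, all component
#' windows fit inside the epoch span, and the component combination is
#' non-empty. Every violation is listed in a single error.
#'
#' @param config A [pipeline_config()].
#' @param epochs An [epoch_set()].
#' @return `config`, unchanged, invisibly raising on any violation.
#' @export
validate_config <- function(config, epochs) {
  stopifnot(inherits(config, "pipeline_config"), inherits(epochs, "epoch_set"))
  problems <- config_problems(config, epochs)
  if (length(problems) > 0) {
    abort(paste0(
      "configuration incompatible with the data:\n",
      paste("-", problems, collapse = "\n")
    ))
  }
  config
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(
    "  bands:", paste(sprintf(
      "%s %g-%g Hz", x$bands$band,
      x$bands$f_low, x$bands$f_high
    ), collapse = ", "), "\n"
  )
  cat(
    "  windows:", paste(sprintf(
      "%s %g-%g ms", x$windows$component,
      x$windows$t_start, x$windows$t_end
    ), collapse = ", "), "\n"
  )
  cat(sprintf(
    "  combo {%s}; sparsity %g; %d surrogates\n",
    paste(x$component_combo, collapse = ","), x$sparsity, x$n_surrogates
  ))
  cat(sprintf(
    "  %s top-%d -> %s; %d-fold CV x %d; seed %d\n",
    x$selector, x$n_top_features, x$classifier,
    x$cv_folds, x$cv_repeats, x$seed
  ))
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML schema mirrors [pipeline_config()] field for field; bands and
#' windows are lists of `{name, f_low, f_high}` / `{name, t_start, t_end}`
#' entries.
#'
#' @param path File path.
#' @return `read_config()` returns a [pipeline_config()];
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  bands <- dplyr::bind_rows(lapply(
    y$bands,
    function(b) band_spec(b$name, b$f_low, b$f_high)
  ))
  windows <- dplyr::bind_rows(lapply(
    y$windows,
    function(w) component_window(w$name, w$t_start, w$t_end)
  ))
  pipeline_config(
    bands = bands, windows = windows,
    component_combo = unlist(y$component_combo),
    sparsity = y$sparsity, n_surrogates = y$n_surrogates,
    n_top_features = y$n_top_features, selector = y$selector,
    classifier = y$classifier, cv_folds = y$cv_folds,
    cv_repeats = y$cv_repeats, cycles = y$cycles, omega0 = y$omega0,
    positive_class = y$positive_class, seed = y$seed
  )
}

#' @rdname read_config
#' @param config A [pipeline_config()] to serialize.
#' @export
write_config <- function(config, path) {
  y <- list(
    bands = lapply(seq_len(nrow(config$bands)), function(i) {
      b <- config$bands[i, ]
      list(name = b$band, f_low = b$f_low, f_high = b$f_high)
    }),
    windows = lapply(seq_len(nrow(config$windows)), function(i) {
      w <- config$windows[i, ]
      list(name = w$component, t_start = w$t_start, t_end = w$t_end)
    }),
    component_combo = config$component_combo,
    sparsity = config$sparsity, n_surrogates = config$n_surrogates,
    n_top_features = config$n_top_features, selector = config$selector,
    classifier = config$classifier, cv_folds = config$cv_folds,
    cv_repeats = config$cv_repeats, cycles = config$cycles,
    omega0 = config$omega0, positive_class = config$positive_class,
    seed = config$seed
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname read_config
#' @details `write_config_template()` writes the package defaults to `path`
#'   as a starting point for editing.
#' @export
write_config_template <- function(path) {
  write_config(pipeline_config(), path)
}
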