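# Readers for the two supported acquisition formats (BrainVision and EDF)
# plus the package's own epoch container (named-dimension array + JSON
# sidecar). Amplitudes are microvolts throughout.

parse_vhdr_ini <- function(lines) {
  section <- ""
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && section != "") {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      out[[section]][[key]] <- val
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' Parses the `.vhdr` header (ASCII or binary data, multiplexed or
#' vectorized orientation, INT_16 or IEEE_FLOAT_32 encoding), the data file,
#' and the `.vmrk` marker file when referenced. Amplitudes are converted to
#' microvolts using each channel's resolution.
#'
#' @param path Path to the `.vhdr` header file.
#' @return A list with `data` (samples x channels matrix, microvolts),
#'   `fs`, `montage`, and `markers` (tibble with `type`, `description`,
#'   `position`).
#' @export
read_brainvision <- function(path) {
  if (!file.exists(path)) abort(sprintf("header file not found: %s", path))
  ini <- parse_vhdr_ini(readLines(path, warn = FALSE))
  ci <- ini[["Common Infos"]]
  if (is.null(ci)) abort(sprintf("%s: missing [Common Infos] section", path))
  need <- function(field) {
    v <- ci[[field]]
    if (is.null(v)) abort(sprintf("%s: missing field %s", path, field))
    v
  }
  n_ch <- as.integer(need("NumberOfChannels"))
  fs <- 1e6 / as.numeric(need("SamplingInterval"))
  dir <- dirname(path)
  data_file <- file.path(dir, need("DataFile"))
  if (!file.exists(data_file)) {
    abort(sprintf("data file not found: %s", data_file))
  }

  chi <- ini[["Channel Infos"]]
  labels <- paste0("ch", seq_len(n_ch))
  resolution <- rep(1, n_ch)
  if (!is.null(chi)) {
    for (k in seq_len(n_ch)) {
      ent <- chi[[paste0("Ch", k)]]
      if (is.null(ent)) next
      parts <- strsplit(ent, ",", fixed = TRUE)[[1]]
      labels[k] <- trimws(parts[1])
      if (length(parts) >= 3 && nzchar(trimws(parts[3]))) {
        resolution[k] <- as.numeric(parts[3])
      }
    }
  }

  fmt <- toupper(ci[["DataFormat"]] %||% "BINARY")
  orientation <- toupper(ci[["DataOrientation"]] %||% "MULTIPLEXED")
  if (fmt == "ASCII") {
    skip <- as.integer(ini[["ASCII Infos"]][["SkipLines"]] %||% "0")
    raw_tab <- utils::read.table(data_file, skip = skip)
    dat <- as.matrix(raw_tab)
  } else {
    bfmt <- toupper(ini[["Binary Infos"]][["BinaryFormat"]] %||% "INT_16")
    sz <- file.info(data_file)$size
    con <- file(data_file, "rb")
    on.exit(close(con))
    if (bfmt == "INT_16") {
      vals <- readBin(con, "integer",
        n = sz / 2, size = 2, signed = TRUE,
        endian = "little"
      )
    } else if (bfmt == "IEEE_FLOAT_32") {
      vals <- readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
    } else {
      abort(sprintf("%s: unsupported BinaryFormat '%s'", path, bfmt))
    }
    n_samp <- length(vals) %/% n_ch
    vals <- vals[seq_len(n_samp * n_ch)]
    dat <- if (orientation == "VECTORIZED") {
      matrix(vals, nrow = n_samp, ncol = n_ch)
    } else {
      t(matrix(vals, nrow = n_ch, ncol = n_samp))
    }
  }
  if (ncol(dat) != n_ch) {
    abort(sprintf(
      "%s: expected %d channels, data file has %d columns",
      path, n_ch, ncol(dat)
    ))
  }
  dat <- sweep(dat, 2, resolution, "*")

  markers <- tibble::tibble(
    type = character(), description = character(),
    position = integer()
  )
  mf <- ci[["MarkerFile"]]
  if (!is.null(mf) && nzchar(mf)) {
    marker_path <- file.path(dir, mf)
    if (!file.exists(marker_path)) {
      abort(sprintf("marker file not found: %s", marker_path))
    }
    mk <- parse_vhdr_ini(readLines(marker_path, warn = FALSE))[["Marker Infos"]]
    if (!is.null(mk)) {
      rows <- lapply(mk, function(ent) {
        parts <- trimws(strsplit(ent, ",", fixed = TRUE)[[1]])
        tibble::tibble(
          type = parts[1], description = parts[2],
          position = as.integer(parts[3])
        )
      })
      markers <- dplyr::bind_rows(rows)
    }
  }
  list(
    data = dat, fs = fs, montage = montage(labels), markers = markers
  )
}

pad_ascii <- function(x, width) {
  formatC(as.character(x), width = width, flag = "-")
}

# Render a numeric so it fits an 8-byte EDF header field, dropping
# precision only as far as needed.
edf_num8 <- function(x) {
  vapply(x, function(v) {
    for (d in 6:1) {
      s <- formatC(v, format = "g", digits = d)
      if (nchar(s) <= 8) return(s)
    }
    s
  }, "")
}

#' Write a continuous recording as EDF
#'
#' Minimal European Data Format writer: one data record spanning the whole
#' signal, 16-bit samples, physical range taken per channel from the data.
#' Intended for interoperability round trips of synthetic recordings.
#'
#' @param data Samples x channels matrix, microvolts.
#' @param fs Sampling rate, Hz.
#' @param path Output `.edf` path.
#' @param channel_names Channel labels (default from column names).
#' @return `path`, invisibly.
#' @export
write_edf <- function(data, fs, path, channel_names = colnames(data)) {
  data <- as.matrix(data)
  n <- nrow(data)
  ns <- ncol(data)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ns))
  pmin_ <- apply(data, 2, min)
  pmax_ <- apply(data, 2, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  # quantize against exactly what lands in the 8-byte header fields
  pmin_ <- as.numeric(edf_num8(pmin_))
  pmax_ <- as.numeric(edf_num8(pmax_))
  pmax_ <- pmax(pmax_, pmin_ + 1e-9)
  dmin <- -32768
  dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad_ascii("0", 8), pad_ascii("synthetic subject", 80),
    pad_ascii("synthetic recording", 80),
    pad_ascii("01.01.00", 8), pad_ascii("00.00.00", 8),
    pad_ascii(256 * (1 + ns), 8), pad_ascii("", 44),
    pad_ascii(1, 8), pad_ascii(edf_num8(n / fs), 8),
    pad_ascii(ns, 4)
  ), con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste(vapply(vals, pad_ascii, "", width = width),
      collapse = ""
    ), con, eos = NULL)
  }
  field(substr(channel_names, 1, 16), 16)
  field(rep("", ns), 80) # transducer
  field(rep("uV", ns), 8)
  field(edf_num8(pmin_), 8)
  field(edf_num8(pmax_), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80) # prefiltering
  field(rep(n, ns), 8)
  field(rep("", ns), 32)
  for (ch in seq_len(ns)) {
    dig <- round((data[, ch] - pmin_[ch]) / (pmax_[ch] - pmin_[ch]) *
      (dmax - dmin) + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_ascii_field <- function(con, width, n = 1) {
  vapply(seq_len(n), function(i) {
    trimws(readChar(con, width, useBytes = TRUE))
  }, "")
}

#' Read an EDF recording
#'
#' Parses the standard EDF header and 16-bit data records, rescaling to
#' physical units. Units are expected to be (micro)volts; amplitudes are
#' returned in microvolts (mV and V are converted).
#'
#' @param path Path to the `.edf` file.
#' @return A list with `data` (samples x channels, microvolts), `fs`, and
#'   `montage`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) abort(sprintf("EDF file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  read_ascii_field(con, 8) # version
  read_ascii_field(con, 80)
  read_ascii_field(con, 80)
  read_ascii_field(con, 8)
  read_ascii_field(con, 8)
  read_ascii_field(con, 8) # header bytes
  read_ascii_field(con, 44)
  # malformed (non-numeric) fields become NA and are rejected explicitly
  n_rec <- suppressWarnings(as.integer(read_ascii_field(con, 8)))
  rec_dur <- suppressWarnings(as.numeric(read_ascii_field(con, 8)))
  ns <- suppressWarnings(as.integer(read_ascii_field(con, 4)))
  if (is.na(ns) || ns < 1) abort(sprintf("%s: malformed signal count", path))
  labels <- read_ascii_field(con, 16, ns)
  read_ascii_field(con, 80, ns)
  units <- read_ascii_field(con, 8, ns)
  pmin_ <- suppressWarnings(as.numeric(read_ascii_field(con, 8, ns)))
  pmax_ <- suppressWarnings(as.numeric(read_ascii_field(con, 8, ns)))
  dmin <- suppressWarnings(as.numeric(read_ascii_field(con, 8, ns)))
  dmax <- suppressWarnings(as.numeric(read_ascii_field(con, 8, ns)))
  read_ascii_field(con, 80, ns)
  spr <- suppressWarnings(as.integer(read_ascii_field(con, 8, ns)))
  read_ascii_field(con, 32, ns)
  if (anyNA(c(pmin_, pmax_, dmin, dmax, spr, n_rec, rec_dur))) {
    abort(sprintf("%s: malformed EDF header (non-numeric field)", path))
  }
  if (length(unique(spr)) != 1) {
    abort(sprintf("%s: differing per-signal sampling rates are not supported", path))
  }
  scale_for_unit <- function(u) {
    u <- tolower(gsub("\u00b5", "u", u))
    if (u %in% c("uv", "")) {
      1
    } else if (u == "mv") {
      1e3
    } else if (u == "v") {
      1e6
    } else {
      abort(sprintf("%s: unknown unit '%s'", path, u))
    }
  }
  unit_scale <- vapply(units, scale_for_unit, numeric(1))
  fs <- spr[1] / rec_dur
  out <- matrix(0, nrow = n_rec * spr[1], ncol = ns)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer",
        n = spr[ch], size = 2, signed = TRUE,
        endian = "little"
      )
      phys <- (dig - dmin[ch]) * (pmax_[ch] - pmin_[ch]) /
        (dmax[ch] - dmin[ch]) + pmin_[ch]
      out[(r - 1) * spr[1] + seq_len(spr[1]), ch] <- phys * unit_scale[ch]
    }
  }
  list(data = out, fs = fs, montage = montage(labels))
}

#' Read a raw recording (format auto-detected)
#'
#' @param path Path to a `.vhdr` (BrainVision) or `.edf` file.
#' @param format `"auto"` (by extension), `"brainvision"` or `"edf"`.
#' @return See [read_brainvision()] / [read_edf()].
#' @export
read_raw <- function(path, format = c("auto", "brainvision", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      vhdr = "brainvision",
      edf = "edf",
      abort(sprintf("cannot infer format from extension '.%s'", ext))
    )
  }
  if (format == "brainvision") read_brainvision(path) else read_edf(path)
}

#' Persist / load an epoch set
#'
#' The amplitude array is stored with named dimensions in RDS form next to
#' a JSON sidecar with sampling rate, epoch timing, labels, montage and
#' package version.
#'
#' @param epochs An [epoch_set()].
#' @param path Base path; `.rds` and `.json` are appended.
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()` the
#'   restored [epoch_set()].
#' @export
write_epochs <- function(epochs, path) {
  saveRDS(epochs$data, paste0(path, ".rds"))
  jsonlite::write_json(
    list(
      fs = epochs$fs, t0 = epochs$t0, labels = epochs$labels,
      channels = epochs$montage$channel_names,
      subject_id = epochs$subject_id,
      package_version = as.character(packageVersion("cohnet"))
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  dat <- readRDS(paste0(path, ".rds"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  epoch_set(dat,
    fs = side$fs, t0 = side$t0, labels = side$labels,
    montage = montage(side$channels), subject_id = side$subject_id
  )
}

#' Write an epoch set as EDF (trials concatenated)
#'
#' Trials are concatenated in time so external tools can inspect the
#' synthetic data; the epoch structure itself is carried by the companion
#' design table, not by the EDF.
#'
#' @param epochs An [epoch_set()].
#' @param path Output `.edf` path.
#' @return `path`, invisibly.
#' @export
write_epochs_edf <- function(epochs, path) {
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[1] * d[3], ncol = d[2])
  write_edf(flat, epochs$fs, path,
    channel_names = epochs$montage$channel_names
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
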