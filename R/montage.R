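#' Electrode montage
#'
#' A montage is the ordered set of scalp-channel labels used to index every
#' connectivity matrix in the pipeline. The order is fixed: permuting the
#' montage together with the data leaves all scalar graph metrics unchanged,
#' but rows/columns of matrices always follow this order.
#'
#' @param channel_names Character vector of unique channel labels.
#' @param positions Optional numeric matrix (channels x 2) of unitless 2D
#'   layout coordinates, used only for plotting.
#' @return An object of class `montage`.
#' @export
#' @examples
#' montage(c("Fz", "Cz", "Pz"))
montage <- function(channel_names, positions = NULL) {
  channel_names <- as.character(channel_names)
  if (anyDuplicated(channel_names)) {
    abort("duplicate channel labels in montage")
  }
  if (length(channel_names) < 1) abort("montage needs at least one channel")
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    stopifnot(nrow(positions) == length(channel_names), ncol(positions) == 2)
    rownames(positions) <- channel_names
  }
  structure(
    list(channel_names = channel_names, positions = positions),
    class = "montage"
  )
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$channel_names), " channels: ",
    paste(head(x$channel_names, 8), collapse = ", "),
    if (length(x$channel_names) > 8) ", ..." else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
length.montage <- function(x) length(x$channel_names)

#' Standard montages for the emotional (30-channel) and cognitive
#' (62-channel) recording setups
#'
#' @param n_channels Either 30 or 62.
#' @return A [montage()].
#' @export
#' @examples
#' standard_montage(30)
standard_montage <- function(n_channels = 30) {
  ch30 <- c(
    "FP1", "FP2", "F3", "Fz", "F4", "FC3", "FCz", "FC4", "F7", "F8",
    "FT7", "FT8", "C3", "Cz", "C4", "CP3", "CPz", "CP4", "T7", "T8",
    "P3", "Pz", "P4", "TP7", "TP8", "P7", "P8", "O1", "Oz", "O2"
  )
  ch62 <- c(
    "Fp1", "Fp2", "AF7", "AF3", "AF4", "AF8", "F9", "F7", "F5", "F3",
    "F1", "Fz", "F2", "F4", "F6", "F8", "F10", "FT7", "FC5", "FC3",
    "FC1", "FCz", "FC2", "FC4", "FC6", "FT8", "C5", "C3", "C1", "Cz",
    "C2", "C4", "C6", "T8", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2",
    "CP4", "CP6", "TP8", "P9", "P7", "P5", "P3", "P1", "Pz", "P2",
    "P4", "P6", "P8", "P10", "PO7", "PO3", "POz", "PO4", "PO8", "O1",
    "Oz", "O2"
  )
  if (n_channels == 30) {
    montage(ch30)
  } else if (n_channels == 62) {
    montage(ch62)
  } else {
    abort("standard_montage() knows the 30- and 62-channel setups only")
  }
}
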