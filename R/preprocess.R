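#' Z-score a signal
#'
#' Centres and scales to zero mean and unit sample standard deviation
#' (`n - 1` divisor, as in [stats::sd()]). A constant signal has no
#' scale and is returned as all zeros with a warning.
#'
#' @param x numeric vector, length >= 2.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' standardize(c(0, 10))  # +/- 0.7071
standardize <- function(x) {
  stopifnot(length(x) >= 2L)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    warning("constant signal: standardize() returns all zeros")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Rescale a signal to the unit interval
#'
#' Affine map sending the minimum to 0 and the maximum to 1. A constant
#' signal maps to all 0.5.
#'
#' @param x numeric vector.
#' @return Numeric vector in `[0, 1]`.
#' @export
#' @examples
#' minmax_01(c(0, 5, 10))
minmax_01 <- function(x) {
  stopifnot(length(x) >= 1L)
  r <- range(x)
  if (r[2] - r[1] == 0) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

.match_channel <- function(channels, role) {
  pat <- switch(role, eog = "eog", eeg = "eeg|fpz|pz")
  hit <- grep(pat, channels, ignore.case = TRUE)
  if (length(hit) == 0L) {
    stop(sprintf("no %s channel found among: %s", toupper(role),
                 paste(channels, collapse = ", ")), call. = FALSE)
  }
  hit[1]
}

#' Assemble scaled model inputs from an epoch dataset
#'
#' Builds the network input tensor for one of the three signal
#' configurations: single-channel EOG, single-channel EEG, or their
#' two-channel combination (EOG stacked first, then EEG). Each epoch of
#' each channel is standardized ([standardize()]) and then rescaled to
#' `[0, 1]` ([minmax_01()]); scaling is per epoch and per channel, so
#' epochs are processed independently.
#'
#' Channels are located by label: a label containing "EOG" fills the EOG
#' role, one containing "EEG" (or the Fpz--Cz/Pz--Oz derivation names)
#' the EEG role.
#'
#' @param epochs an `"epoch_dataset"` from [segment_epochs()] or
#'   [generate_dataset()].
#' @param selection `"eog"`, `"eeg"`, or `"eog+eeg"`.
#' @return Object of class `"model_input"`: a numeric array of dimension
#'   `(n_epochs, n_channels, samples_per_epoch)` with all values in
#'   `[0, 1]`, with attributes `selection` and `channels`.
#' @export
assemble_inputs <- function(epochs, selection = c("eeg", "eog", "eog+eeg")) {
  stopifnot(inherits(epochs, "epoch_dataset"))
  selection <- match.arg(selection)
  roles <- strsplit(selection, "+", fixed = TRUE)[[1]]
  cols <- vapply(roles, function(r) .match_channel(epochs$channels, r), 0L)
  n <- dim(epochs$signals)[1]
  spe <- dim(epochs$signals)[3]
  out <- array(NA_real_, dim = c(n, length(cols), spe))
  for (j in seq_along(cols)) {
    for (i in seq_len(n)) {
      out[i, j, ] <- minmax_01(standardize(epochs$signals[i, cols[j], ]))
    }
  }
  structure(out, selection = selection,
            channels = epochs$channels[cols], class = "model_input")
}

#' @export
print.model_input <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<model_input> %d epochs x %d channel(s) x %d samples, values in [0,1]\n",
              d[1], d[2], d[3]))
  cat("  selection:", attr(x, "selection"),
      "| channels:", paste(attr(x, "channels"), collapse = ", "), "\n")
  invisible(x)
}
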