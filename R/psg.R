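#' Construct a PSG record
#'
#' Container for multichannel raw polysomnography signals. All channels
#' must share one sampling rate and one length; the target databases use
#' 100 Hz EEG (Fpz--Cz) and horizontal EOG.
#'
#' @param signals named list of numeric vectors (physical units, uV).
#' @param fs sampling rate in Hz.
#' @param record_id identifier string.
#' @param start_time recording start, seconds since the Unix epoch, or
#'   `NA` if unknown.
#' @return Object of class `"psg_record"`.
#' @export
psg_record <- function(signals, fs, record_id = "record", start_time = NA_real_) {
  stopifnot(is.list(signals), !is.null(names(signals)), all(nzchar(names(signals))))
  if (length(signals) > 0L && length(unique(lengths(signals))) != 1L) {
    stop("all channels must have identical length", call. = FALSE)
  }
  structure(
    list(record_id = record_id, signals = signals,
         channels = names(signals), fs = fs, start_time = start_time),
    class = "psg_record"
  )
}

#' @export
print.psg_record <- function(x, ...) {
  n <- if (length(x$signals) > 0L) length(x$signals[[1]]) else 0L
  cat(sprintf("<psg_record> '%s': %d channel(s) @ %g Hz, %d samples (%.1f s)\n",
              x$record_id, length(x$channels), x$fs, n, n / x$fs))
  for (ch in x$channels) cat("  -", ch, "\n")
  invisible(x)
}

#' Read PSG channels from an EDF/EDF+ file
#'
#' Loads the requested channels only, in the requested order, converted
#' to physical units by the EDF header scaling. No resampling or
#' filtering is performed. All requested channels must share one
#' sampling rate.
#'
#' @param path path to an EDF or EDF+ file.
#' @param channel_labels character vector of channel labels to load
#'   (matched exactly after trimming padding). An empty vector yields a
#'   record with zero channels.
#' @return A [psg_record()].
#' @export
read_psg <- function(path, channel_labels) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  hdr <- .edf_header(path)
  if (length(channel_labels) == 0L) {
    return(psg_record(structure(list(), names = character()),
                      fs = NA_real_, record_id = hdr$recording,
                      start_time = .edf_start_time(hdr)))
  }
  idx <- match(channel_labels, hdr$labels)
  if (anyNA(idx)) {
    stop(sprintf("channel(s) not found in '%s': %s (available: %s)",
                 path,
                 paste(channel_labels[is.na(idx)], collapse = ", "),
                 paste(hdr$labels, collapse = ", ")),
         call. = FALSE)
  }
  fs <- hdr$samples_per_record[idx] / hdr$record_duration
  if (length(unique(fs)) != 1L) {
    stop("requested channels have different sampling rates", call. = FALSE)
  }
  dat <- .edf_data(path, hdr, want = idx)
  signals <- vector("list", length(idx))
  names(signals) <- channel_labels
  for (j in seq_along(idx)) {
    s <- idx[j]
    gain <- (hdr$phys_max[s] - hdr$phys_min[s]) / (hdr$dig_max[s] - hdr$dig_min[s])
    signals[[j]] <- hdr$phys_min[s] + (dat[[s]] - hdr$dig_min[s]) * gain
  }
  psg_record(signals, fs = fs[1], record_id = hdr$recording,
             start_time = .edf_start_time(hdr))
}

#' Construct a hypnogram
#'
#' A hypnogram is an ordered set of stage events `(onset, duration,
#' stage)`, onsets in seconds from record start. Events must be in
#' temporal order and non-overlapping.
#'
#' @param onset numeric vector of onsets (s).
#' @param duration numeric vector of positive durations (s).
#' @param stage stage labels (character or factor, see [parse_stage()]).
#' @return Data frame of class `"hypnogram"`.
#' @export
hypnogram <- function(onset, duration, stage) {
  stage <- as_stage(stage)
  stopifnot(length(onset) == length(duration), length(onset) == length(stage))
  if (any(duration <= 0)) stop("event durations must be positive", call. = FALSE)
  if (is.unsorted(onset)) stop("event onsets must be non-decreasing", call. = FALSE)
  if (length(onset) > 1L &&
      any(onset[-1] < (onset + duration)[-length(onset)] - 1e-9)) {
    stop("hypnogram events overlap", call. = FALSE)
  }
  structure(
    data.frame(onset = as.numeric(onset), duration = as.numeric(duration),
               stage = stage),
    class = c("hypnogram", "data.frame")
  )
}

#' Read a hypnogram from file
#'
#' Accepts either an EDF+ file with an `"EDF Annotations"` signal (the
#' format of the sleep-edfx hypnograms) or a plain text file with one
#' stage token per line (one token per 30-s epoch, the older per-epoch
#' convention). Stage tokens are matched case-insensitively after
#' stripping the `"Sleep stage "` prefix; unknown tokens (`?`, `X`, ...)
#' map to `UNSCORED`.
#'
#' @param path input file.
#' @param epoch_len epoch length in seconds used to assign onsets and
#'   durations when reading a per-line label file.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_len = 30) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  if (.is_edf(path)) {
    hdr <- .edf_header(path)
    ann <- which(hdr$labels == "EDF Annotations")
    if (length(ann) == 0L) {
      stop(sprintf("'%s' is EDF but has no 'EDF Annotations' signal", path),
           call. = FALSE)
    }
    as_raw <- rep(FALSE, hdr$ns); as_raw[ann] <- TRUE
    dat <- .edf_data(path, hdr, want = ann, as_raw = as_raw)
    tals <- do.call(rbind, lapply(ann, function(s) .parse_tals(dat[[s]])))
    tals <- tals[order(tals$onset), , drop = FALSE]
    if (nrow(tals) == 0L) stop("no stage annotations found", call. = FALSE)
    hypnogram(tals$onset, tals$duration, parse_stage(tals$text))
  } else {
    tokens <- readLines(path, warn = FALSE)
    tokens <- trimws(tokens)
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) == 0L) stop(sprintf("empty label file: '%s'", path), call. = FALSE)
    n <- length(tokens)
    hypnogram(onset = (seq_len(n) - 1) * epoch_len,
              duration = rep(epoch_len, n),
              stage = parse_stage(tokens))
  }
}

#' Expand a hypnogram to one label per epoch
#'
#' Epoch windows are half-open, 0-based: epoch `i` covers
#' `[i*epoch_len, (i+1)*epoch_len)` seconds. An event whose duration is
#' not a multiple of `epoch_len` is truncated to complete epochs with a
#' warning.
#'
#' @param h a [hypnogram()].
#' @param epoch_len epoch length in seconds (default 30).
#' @return Factor of per-epoch stage labels over [stage_levels()].
#' @export
#' @examples
#' h <- hypnogram(0, 90, "W")
#' expand_hypnogram(h)  # [W, W, W]
expand_hypnogram <- function(h, epoch_len = 30) {
  stopifnot(inherits(h, "hypnogram"), epoch_len > 0)
  if (nrow(h) == 0L) return(factor(character(), levels = stage_levels()))
  ends <- h$onset + h$duration
  if (nrow(h) > 1L && any(h$onset[-1] < ends[-nrow(h)] - 1e-9)) {
    stop("hypnogram events overlap", call. = FALSE)
  }
  if (nrow(h) > 1L && any(abs(h$onset[-1] - ends[-nrow(h)]) > 1e-9)) {
    warning("hypnogram has gaps between events; epoch indices follow event order")
  }
  reps <- h$duration %/% epoch_len
  if (any(h$duration %% epoch_len > 1e-9)) {
    warning(sprintf(
      "%d event(s) truncated to complete %g-s epochs",
      sum(h$duration %% epoch_len > 1e-9), epoch_len))
  }
  factor(rep(as.character(h$stage), reps), levels = stage_levels())
}

#' Segment a PSG record into labelled fixed-length epochs
#'
#' Divides each channel into consecutive windows of `epoch_len` seconds
#' (3000 samples at 100 Hz for the standard 30-s epoch) aligned with the
#' per-epoch labels; a trailing partial window is dropped.
#'
#' @param rec a [psg_record()].
#' @param labels per-epoch stage labels (from [expand_hypnogram()]).
#' @param epoch_len epoch length in seconds.
#' @return Object of class `"epoch_dataset"`: a list with `signals`, an
#'   array of dimension `(n_epochs, n_channels, samples_per_epoch)`;
#'   `labels`, a factor over [stage_levels()]; and `channels`, `fs`,
#'   `epoch_len`.
#' @export
segment_epochs <- function(rec, labels, epoch_len = 30) {
  stopifnot(inherits(rec, "psg_record"))
  labels <- as_stage(labels)
  if (length(rec$signals) == 0L) stop("record has no channels", call. = FALSE)
  spe <- as.integer(round(epoch_len * rec$fs))
  n_sig <- length(rec$signals[[1]])
  n_max <- n_sig %/% spe
  n <- min(length(labels), n_max)
  if (n == 0L) {
    stop(sprintf(
      "no usable epochs: %d samples give %d complete %g-s epochs, %d labels supplied",
      n_sig, n_max, epoch_len, length(labels)), call. = FALSE)
  }
  if (length(labels) > n_max) {
    warning(sprintf("more labels (%d) than complete epochs (%d); extra labels dropped",
                    length(labels), n_max))
  }
  x <- array(NA_real_, dim = c(n, length(rec$channels), spe))
  for (j in seq_along(rec$channels)) {
    seg <- matrix(rec$signals[[j]][seq_len(n * spe)], nrow = spe)
    x[, j, ] <- t(seg)
  }
  structure(
    list(signals = x, labels = labels[seq_len(n)],
         channels = rec$channels, fs = rec$fs, epoch_len = epoch_len),
    class = "epoch_dataset"
  )
}

#' @export
print.epoch_dataset <- function(x, ...) {
  cat(sprintf("<epoch_dataset> %d epochs x %d channel(s) x %d samples (%g s @ %g Hz)\n",
              dim(x$signals)[1], dim(x$signals)[2], dim(x$signals)[3],
              x$epoch_len, x$fs))
  print(class_distribution(x$labels))
  invisible(x)
}
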