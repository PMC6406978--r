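# Minimal EDF / EDF+ I/O.
#
# EDF stores a 256-byte ASCII header, 256 further bytes per signal, then
# data records of little-endian 16-bit integers (one block per signal per
# record), scaled linearly between the digital and physical ranges
# declared in the header. EDF+ adds an "EDF Annotations" signal whose
# bytes hold time-stamped annotation lists (TALs):
#   +onset[\x15duration]\x14text\x14 ... \x00
# Only the subset needed for PSG signals and hypnogram events is
# implemented here.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)
}

.edf_num <- function(x, width) {
  s <- formatC(x, format = "fg", width = 1, digits = 8)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  .edf_pad(s, width)
}

.read_ascii <- function(con, n) {
  rawToChar(readBin(con, "raw", n = n))
}

.edf_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ver_raw <- readBin(con, "raw", n = 8L)
  if (length(ver_raw) < 8L || any(ver_raw > as.raw(127L)) ||
      !identical(trimws(rawToChar(ver_raw)), "0")) {
    stop(sprintf("'%s' is not an EDF file (bad version field)", path), call. = FALSE)
  }
  patient <- trimws(.read_ascii(con, 80L))
  recording <- trimws(.read_ascii(con, 80L))
  startdate <- trimws(.read_ascii(con, 8L))
  starttime <- trimws(.read_ascii(con, 8L))
  header_bytes <- as.integer(.read_ascii(con, 8L))
  reserved <- trimws(.read_ascii(con, 44L))
  n_records <- as.integer(.read_ascii(con, 8L))
  record_duration <- as.numeric(.read_ascii(con, 8L))
  ns <- as.integer(.read_ascii(con, 4L))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header: no signals", call. = FALSE)
  field <- function(w) {
    vapply(seq_len(ns), function(i) trimws(.read_ascii(con, w)), character(1))
  }
  labels <- field(16L)
  transducer <- field(80L)
  phys_dim <- field(8L)
  phys_min <- as.numeric(field(8L))
  phys_max <- as.numeric(field(8L))
  dig_min <- as.numeric(field(8L))
  dig_max <- as.numeric(field(8L))
  prefilter <- field(80L)
  spr <- as.integer(field(8L))
  field(32L) # per-signal reserved
  list(
    patient = patient, recording = recording,
    startdate = startdate, starttime = starttime,
    header_bytes = header_bytes, reserved = reserved,
    n_records = n_records, record_duration = record_duration,
    ns = ns, labels = labels, transducer = transducer, phys_dim = phys_dim,
    phys_min = phys_min, phys_max = phys_max,
    dig_min = dig_min, dig_max = dig_max,
    prefilter = prefilter, samples_per_record = spr
  )
}

# Reads the full data block as a list of per-signal int vectors (numeric,
# still digital units) or raw vectors for annotation signals.
.edf_data <- function(path, hdr, want = seq_len(hdr$ns), as_raw = logical(hdr$ns)) {
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, hdr$header_bytes)
  spr <- hdr$samples_per_record
  rec_len <- sum(spr)
  raw_all <- readBin(con, "raw", n = 2L * rec_len * hdr$n_records)
  n_rec <- length(raw_all) %/% (2L * rec_len)
  if (n_rec < hdr$n_records) {
    warning(sprintf("EDF file '%s' truncated: %d of %d records present",
                    path, n_rec, hdr$n_records))
  }
  offs <- c(0L, cumsum(spr))
  out <- vector("list", hdr$ns)
  for (s in want) {
    # byte indices of signal s within each record
    idx <- as.vector(outer(
      seq_len(2L * spr[s]) + 2L * offs[s],
      (seq_len(n_rec) - 1L) * 2L * rec_len,
      `+`
    ))
    bytes <- raw_all[idx]
    if (as_raw[s]) {
      out[[s]] <- bytes
    } else {
      out[[s]] <- readBin(bytes, "integer", n = length(bytes) %/% 2L,
                          size = 2L, signed = TRUE, endian = "little")
    }
  }
  out
}

.edf_start_time <- function(hdr) {
  dt <- try(as.POSIXct(paste(hdr$startdate, hdr$starttime),
                       format = "%d.%m.%y %H.%M.%S", tz = "UTC"), silent = TRUE)
  if (inherits(dt, "try-error") || is.na(dt)) NA_real_ else as.numeric(dt)
}

#' Write signals to an EDF file
#'
#' Writes a set of equally sampled channels as standard 16-bit EDF. Each
#' channel is scaled to its own physical min/max, so the quantisation
#' step is `(max - min) / (2^16 - 1)`.
#'
#' @param signals named list of numeric vectors (equal lengths), in
#'   physical units (microvolts for PSG).
#' @param fs sampling rate in Hz, shared by all channels.
#' @param path output file path.
#' @param record_duration data-record length in seconds; must divide the
#'   total duration.
#' @param record_id recording identification string.
#' @param phys_dim physical dimension label (default `"uV"`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, fs, path, record_duration = 30,
                      record_id = "synthetic", phys_dim = "uV") {
  stopifnot(is.list(signals), length(signals) >= 1L, !is.null(names(signals)))
  n <- unique(lengths(signals))
  if (length(n) != 1L) stop("all channels must have the same length", call. = FALSE)
  spr <- as.integer(round(record_duration * fs))
  if (n %% spr != 0L) {
    stop("signal length must be a whole number of data records", call. = FALSE)
  }
  n_rec <- n %/% spr
  ns <- length(signals)

  pmin <- vapply(signals, min, 0)
  pmax <- vapply(signals, max, 0)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeBin(charToRaw(.edf_pad(x, w)), con)
  wr("0", 8L)
  wr(record_id, 80L)
  wr(record_id, 80L)
  wr("01.01.00", 8L)
  wr("00.00.00", 8L)
  wr(256L * (1L + ns), 8L)
  wr("", 44L)
  wr(n_rec, 8L)
  wr(.edf_num(record_duration, 8L), 8L)
  wr(ns, 4L)
  for (lab in names(signals)) wr(lab, 16L)
  for (i in seq_len(ns)) wr("", 80L)
  for (i in seq_len(ns)) wr(phys_dim, 8L)
  for (i in seq_len(ns)) wr(.edf_num(pmin[i], 8L), 8L)
  for (i in seq_len(ns)) wr(.edf_num(pmax[i], 8L), 8L)
  for (i in seq_len(ns)) wr(dmin, 8L)
  for (i in seq_len(ns)) wr(dmax, 8L)
  for (i in seq_len(ns)) wr("", 80L)
  for (i in seq_len(ns)) wr(spr, 8L)
  for (i in seq_len(ns)) wr("", 32L)

  # re-read the truncated header fields so the scaling used for encoding
  # matches exactly what a reader will decode with
  pmin_w <- as.numeric(vapply(pmin, function(x) .edf_num(x, 8L), ""))
  pmax_w <- as.numeric(vapply(pmax, function(x) .edf_num(x, 8L), ""))

  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    d <- round((signals[[i]] - pmin_w[i]) / (pmax_w[i] - pmin_w[i]) *
                 (dmax - dmin) + dmin)
    dig[[i]] <- as.integer(pmin(pmax(d, dmin), dmax))
  }
  for (r in seq_len(n_rec)) {
    sl <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(ns)) {
      writeBin(dig[[i]][sl], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

.stage_to_edf_text <- function(stage) {
  map <- c(W = "Sleep stage W", S1 = "Sleep stage 1", S2 = "Sleep stage 2",
           S3 = "Sleep stage 3", S4 = "Sleep stage 4", REM = "Sleep stage R",
           MOVEMENT = "Movement time", UNSCORED = "Sleep stage ?")
  unname(map[as.character(stage)])
}

#' Write a hypnogram as an EDF+ annotation file
#'
#' Produces a minimal EDF+ file containing a single `"EDF Annotations"`
#' signal whose time-stamped annotation lists encode the stage events, in
#' the style of the hypnogram files distributed with the public sleep-EDF
#' databases.
#'
#' @param h a [hypnogram()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hypnogram_edf <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  total <- if (nrow(h) > 0L) max(h$onset + h$duration) else 1
  tal <- function(onset, duration, text) {
    c(charToRaw(sprintf("+%s", format(onset, scientific = FALSE))),
      as.raw(0x15), charToRaw(format(duration, scientific = FALSE)),
      as.raw(0x14), charToRaw(text), as.raw(0x14), as.raw(0x00))
  }
  bytes <- c(charToRaw("+0"), as.raw(0x14), as.raw(0x14), as.raw(0x00))
  for (i in seq_len(nrow(h))) {
    bytes <- c(bytes, tal(h$onset[i], h$duration[i],
                          .stage_to_edf_text(h$stage[i])))
  }
  if (length(bytes) %% 2L == 1L) bytes <- c(bytes, as.raw(0x00))
  spr <- length(bytes) %/% 2L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeBin(charToRaw(.edf_pad(x, w)), con)
  wr("0", 8L)
  wr("hypnogram", 80L)
  wr("hypnogram", 80L)
  wr("01.01.00", 8L)
  wr("00.00.00", 8L)
  wr(256L * 2L, 8L)
  wr("EDF+C", 44L)
  wr(1L, 8L)
  wr(.edf_num(total, 8L), 8L)
  wr(1L, 4L)
  wr("EDF Annotations", 16L)
  wr("", 80L)
  wr("", 8L)
  wr(-1, 8L)
  wr(1, 8L)
  wr(-32768, 8L)
  wr(32767, 8L)
  wr("", 80L)
  wr(spr, 8L)
  wr("", 32L)
  writeBin(bytes, con)
  invisible(path)
}

# Parse the TAL byte stream of the annotation signals of an EDF+ file
# into (onset, duration, text) rows. Time-keeping TALs (empty text) are
# dropped.
.parse_tals <- function(bytes) {
  # TALs are nul-terminated; R strings cannot hold nuls, so split the
  # raw stream first
  nul <- which(bytes == as.raw(0))
  starts <- c(1L, nul + 1L)
  ends <- c(nul - 1L, length(bytes))
  chunks <- character(0)
  for (i in seq_along(starts)) {
    if (ends[i] >= starts[i]) {
      chunks <- c(chunks, rawToChar(bytes[starts[i]:ends[i]]))
    }
  }
  out <- list()
  for (ch in chunks) {
    if (!nzchar(ch)) next
    m <- regmatches(ch, regexec(
      "^([+-][0-9]+(?:\\.[0-9]+)?)(?:\x15([0-9]+(?:\\.[0-9]+)?))?\x14(.*)$",
      ch))[[1]]
    if (length(m) == 0L) next
    onset <- as.numeric(m[2])
    duration <- if (nzchar(m[3])) as.numeric(m[3]) else 0
    texts <- strsplit(m[4], "\x14", fixed = TRUE)[[1]]
    texts <- texts[nzchar(texts)]
    for (tx in texts) {
      out[[length(out) + 1L]] <- data.frame(
        onset = onset, duration = duration, text = tx,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(onset = numeric(), duration = numeric(),
                      text = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

.is_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = 8L)
  length(head) == 8L && all(head <= as.raw(127L)) &&
    identical(trimws(rawToChar(head)), "0")
}
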