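test_that("EDF write-then-read round trip is exact up to 16-bit quantization", {
  fs <- 100
  t <- (0:(60 * fs - 1)) / fs
  x <- 75 * sin(2 * pi * 1 * t)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(list("EEG Fpz-Cz" = x), fs = fs, path = path)
  rec <- read_psg(path, "EEG Fpz-Cz")
  expect_s3_class(rec, "psg_record")
  expect_equal(rec$fs, 100)
  expect_length(rec$signals[[1]], 6000)
  step <- diff(range(x)) / (2^16 - 1)
  expect_lt(max(abs(rec$signals[[1]] - x)), 2 * step)
})

test_that("requested channels come back in requested order, others untouched", {
  fs <- 100
  sig <- list("EOG horizontal" = sin(1:3000), "EEG Fpz-Cz" = cos(1:3000))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(sig, fs = fs, path = path)
  rec <- read_psg(path, c("EEG Fpz-Cz", "EOG horizontal"))
  expect_identical(rec$channels, c("EEG Fpz-Cz", "EOG horizontal"))
  expect_lt(max(abs(rec$signals[["EEG Fpz-Cz"]] - cos(1:3000))), 1e-3)
})

test_that("missing channels and empty requests are handled per contract", {
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(list("EOG horizontal" = sin(1:3000)), fs = 100, path = path)
  expect_error(read_psg(path, "Fpz-Cz"), "Fpz-Cz")
  rec <- read_psg(path, character())
  expect_length(rec$channels, 0)
  expect_error(read_psg(withr::local_tempfile(), "x"), "not found")
})

test_that("non-EDF input is rejected with a format error", {
  path <- withr::local_tempfile(fileext = ".edf")
  writeBin(as.raw(rep(255, 600)), path)
  expect_error(read_psg(path, "EEG"), "not an EDF")
})

test_that("EDF+ hypnograms round trip through the annotation writer", {
  h <- hypnogram(onset = c(0, 1800, 1830),
                 duration = c(1800, 30, 60),
                 stage = c("W", "S1", "REM"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_hypnogram_edf(h, path)
  h2 <- read_hypnogram(path)
  expect_s3_class(h2, "hypnogram")
  expect_equal(h2$onset, h$onset)
  expect_equal(h2$duration, h$duration)
  expect_equal(as.character(h2$stage), c("W", "S1", "REM"))
})

test_that("plain per-line label files are read with ambiguous tokens mapped", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("W", "S2", "?", "M", "X"), path)
  h <- read_hypnogram(path)
  expect_equal(nrow(h), 5)
  expect_equal(h$onset, c(0, 30, 60, 90, 120))
  expect_true(all(h$duration == 30))
  expect_equal(as.character(h$stage),
               c("W", "S2", "UNSCORED", "MOVEMENT", "UNSCORED"))
})

test_that("stage token parsing strips the EDF+ prefix and is case-insensitive", {
  expect_equal(as.character(parse_stage("Sleep stage W")), "W")
  expect_equal(as.character(parse_stage(c("Sleep stage 1", "sleep stage R"))),
               c("S1", "REM"))
  expect_equal(as.character(parse_stage("?")), "UNSCORED")
  expect_equal(as.character(parse_stage("M")), "MOVEMENT")
  expect_equal(as.character(parse_stage("Movement time")), "MOVEMENT")
})

test_that("expand_hypnogram yields one label per epoch with truncation warning", {
  expect_equal(as.character(expand_hypnogram(hypnogram(0, 90, "W"))),
               c("W", "W", "W"))
  h <- hypnogram(c(0, 30), c(30, 30), c("W", "S2"))
  expect_equal(as.character(expand_hypnogram(h)), c("W", "S2"))
  expect_warning(lab <- expand_hypnogram(hypnogram(0, 45, "W")), "truncated")
  expect_equal(as.character(lab), "W")
  # length == sum(duration) / epoch_len for conforming hypnograms
  h3 <- hypnogram(c(0, 60, 90), c(60, 30, 150), c("W", "S1", "S2"))
  expect_length(expand_hypnogram(h3), sum(h3$duration) / 30)
})

test_that("overlapping events are rejected", {
  expect_error(hypnogram(c(0, 20), c(30, 30), c("W", "S1")), "overlap")
})

test_that("segment_epochs cuts complete 3000-sample epochs and drops the tail", {
  fs <- 100
  rec <- psg_record(list("EEG Fpz-Cz" = rnorm(90 * fs)), fs = fs)
  ds <- segment_epochs(rec, parse_stage(c("W", "W", "S1")))
  expect_s3_class(ds, "epoch_dataset")
  expect_equal(dim(ds$signals), c(3, 1, 3000))
  # concatenating the epochs reproduces the leading prefix of the raw signal
  expect_identical(as.vector(t(ds$signals[, 1, ])), rec$signals[[1]][1:9000])

  rec100 <- psg_record(list("EEG Fpz-Cz" = rnorm(100 * fs)), fs = fs)
  ds100 <- segment_epochs(rec100, parse_stage(c("W", "W", "W")))
  expect_equal(dim(ds100$signals)[1], 3)  # final 10 s discarded
})

test_that("a recording shorter than one epoch is an empty-dataset error", {
  rec <- psg_record(list("EEG Fpz-Cz" = rnorm(2900)), fs = 100)
  expect_error(segment_epochs(rec, parse_stage("W")), "no usable epochs")
})
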