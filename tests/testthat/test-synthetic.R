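test_that("hypnogram simulation is a seeded Markov chain starting in wake", {
  cfg <- synth_config(n_epochs = 50, seed = 21)
  h1 <- generate_hypnogram(cfg)
  h2 <- generate_hypnogram(cfg)
  expect_identical(h1, h2)  # deterministic given the seed
  expect_equal(nrow(h1), 50)
  expect_equal(as.character(h1$stage[1]), "W")
  expect_true(all(h1$duration == 30))
  expect_equal(h1$onset, (0:49) * 30)

  # absorbing chain: identity transitions keep the start state
  ident <- diag(6)
  dimnames(ident) <- list(scoreable_stages(), scoreable_stages())
  hW <- generate_hypnogram(synth_config(n_epochs = 20, transition = ident, seed = 3))
  expect_true(all(hW$stage == "W"))

  bad <- matrix(1, 6, 6)
  expect_error(synth_config(transition = bad), "summing to 1")
})

test_that("uniform transitions visit each stage at its binomial rate", {
  unif <- matrix(1 / 6, 6, 6)
  dimnames(unif) <- list(scoreable_stages(), scoreable_stages())
  n <- 6000
  h <- generate_hypnogram(synth_config(n_epochs = n, transition = unif, seed = 8))
  counts <- table(factor(h$stage, levels = scoreable_stages()))
  sd3 <- 3 * sqrt(n * (1 / 6) * (5 / 6))
  expect_true(all(abs(counts - n / 6) < sd3))
})

test_that("stage signatures separate delta and alpha band power", {
  set.seed(42)
  n <- 200
  d_s4 <- numeric(n); d_w <- numeric(n)
  a_s4 <- numeric(n); a_w <- numeric(n)
  for (i in seq_len(n)) {
    s4 <- generate_epoch("S4", "eeg")
    w <- generate_epoch("W", "eeg")
    d_s4[i] <- band_power(s4, 100, 0.5, 2)
    d_w[i] <- band_power(w, 100, 0.5, 2)
    a_s4[i] <- band_power(s4, 100, 8, 12)
    a_w[i] <- band_power(w, 100, 8, 12)
  }
  expect_gte(mean(d_s4 > d_w), 0.95)  # deep sleep dominates delta
  expect_gte(mean(a_w > a_s4), 0.95)  # wake dominates alpha
})

test_that("a silent model yields an all-zero epoch; unknown stages error", {
  quiet <- default_signal_model()
  for (st in names(quiet)) {
    for (ch in names(quiet[[st]])) {
      quiet[[st]][[ch]]$osc$amp <- rep(0, nrow(quiet[[st]][[ch]]$osc))
      quiet[[st]][[ch]]$bursts <- quiet[[st]][[ch]]$bursts[0, ]
      quiet[[st]][[ch]]$noise_sd <- 0
    }
  }
  expect_equal(generate_epoch("S2", "eeg", model = quiet, seed = 1), rep(0, 3000))
  expect_error(generate_epoch("N3", "eeg"), "unknown stage")
})

test_that("generate_dataset produces aligned labelled epochs deterministically", {
  cfg <- synth_config(n_epochs = 10, seed = 14)
  ds <- generate_dataset(cfg)
  expect_s3_class(ds, "epoch_dataset")
  expect_equal(dim(ds$signals), c(10, 2, 3000))
  hyp <- attr(ds, "hypnogram")
  expect_identical(as.character(ds$labels), as.character(hyp$stage))
  # class counts match the hypnogram exactly, by construction
  expect_equal(table(ds$labels), table(hyp$stage))
  ds2 <- generate_dataset(cfg)
  expect_identical(ds$signals, ds2$signals)
})

test_that("a written dataset round-trips through the PSG reader", {
  cfg <- synth_config(n_epochs = 6, seed = 2)
  dir <- withr::local_tempdir()
  ds <- generate_dataset(cfg, dir = dir)
  files <- attr(ds, "files")
  expect_true(all(file.exists(files)))

  rec <- read_psg(files[["psg"]], c("EOG horizontal", "EEG Fpz-Cz"))
  labels <- expand_hypnogram(read_hypnogram(files[["labels"]]))
  expect_identical(as.character(labels), as.character(ds$labels))
  ds_rt <- segment_epochs(rec, labels)
  for (j in 1:2) {
    rng <- range(ds$signals[, j, ])
    step <- diff(rng) / (2^16 - 1)
    expect_lt(max(abs(ds_rt$signals[, j, ] - ds$signals[, j, ])), 2 * step)
  }
  # the EDF+ hypnogram carries the same stages
  h_edf <- read_hypnogram(files[["hypnogram"]])
  expect_identical(as.character(h_edf$stage), as.character(ds$labels))
})

test_that("the imbalanced option is wake-dominated like overnight databases", {
  cfg <- synth_config(n_epochs = 2000, transition = imbalanced_transition(),
                      seed = 5)
  h <- generate_hypnogram(cfg)
  d <- class_distribution(h$stage)
  expect_gt(d$percent[d$stage == "W"], 45)
})
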