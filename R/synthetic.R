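# Synthetic stage-labelled PSG. The generator is a test-data fixture
# with enough spectral structure to be learnable, not a physiological
# simulation: each stage/channel pair is a sum of narrow-band sinusoids
# (randomised frequency and phase per epoch), transient bursts (sleep
# spindles, eye movements, blinks) and white noise.

.synth_stages <- function() scoreable_stages()

#' Default stage-signature signal model
#'
#' Textbook spectral signatures, per stage and channel role:
#' wake carries dominant alpha (8--12 Hz) EEG and blink-like EOG
#' transients; S1 slows to theta; S2 adds 12--14 Hz spindle bursts; S3
#' and S4 are dominated by high-amplitude delta (0.5--2 Hz), strongest
#' in S4; REM has low-amplitude mixed-frequency EEG with large slow EOG
#' deflections (rapid eye movements). Amplitudes are in microvolts.
#'
#' @return Nested list: `model[[stage]][[role]]` with elements `osc`
#'   (data frame `freq`, `jitter`, `amp`), `bursts` (data frame `freq`,
#'   `rate`, `dur`, `amp`) and `noise_sd`. Roles are `"eeg"` and
#'   `"eog"`.
#' @export
default_signal_model <- function() {
  osc <- function(...) {
    d <- data.frame(...)
    names(d) <- c("freq", "jitter", "amp")[seq_len(ncol(d))]
    d
  }
  bursts <- function(freq = numeric(), rate = numeric(), dur = numeric(),
                     amp = numeric()) {
    data.frame(freq = freq, rate = rate, dur = dur, amp = amp)
  }
  chan <- function(o, b, noise_sd) list(osc = o, bursts = b, noise_sd = noise_sd)
  list(
    W = list(
      eeg = chan(osc(c(10, 20), c(1, 2), c(30, 8)), bursts(), 8),
      eog = chan(osc(numeric(), numeric(), numeric()),
                 bursts(1.2, 0.3, 0.4, 80), 10)
    ),
    S1 = list(
      eeg = chan(osc(c(5, 9), c(1, 1), c(25, 8)), bursts(), 8),
      eog = chan(osc(0.4, 0.1, 40), bursts(), 10)
    ),
    S2 = list(
      eeg = chan(osc(4.5, 1, 22), bursts(13, 0.12, 1.0, 45), 8),
      eog = chan(osc(0.3, 0.1, 10), bursts(), 10)
    ),
    S3 = list(
      eeg = chan(osc(c(1.5, 5), c(0.5, 1), c(60, 8)), bursts(), 8),
      eog = chan(osc(1.5, 0.5, 20), bursts(), 10)
    ),
    S4 = list(
      eeg = chan(osc(0.75, 0.25, 90), bursts(), 8),
      eog = chan(osc(0.75, 0.25, 25), bursts(), 10)
    ),
    REM = list(
      eeg = chan(osc(5.5, 1, 18), bursts(), 8),
      eog = chan(osc(numeric(), numeric(), numeric()),
                 bursts(1.5, 0.4, 0.8, 120), 10)
    )
  )
}

#' Default stage-transition matrix
#'
#' A sticky Markov chain over the six stages with an exactly known
#' stationary distribution: `P = p * I + (1 - p) * 1 pi'`, i.e. with
#' probability `p` the stage persists and otherwise the next stage is an
#' independent draw from `pi`. The stationary law of this chain is `pi`
#' itself. The default `pi` gives a roughly balanced five-class problem
#' after the S3+S4 merge.
#'
#' @param persistence probability of staying by inertia (default 0.4).
#' @param stationary named stationary probabilities over the six stages.
#' @return Row-stochastic 6 x 6 matrix with stage dimnames.
#' @export
default_transition <- function(persistence = 0.4,
                               stationary = c(W = 0.22, S1 = 0.18, S2 = 0.20,
                                              S3 = 0.09, S4 = 0.09, REM = 0.22)) {
  stopifnot(persistence >= 0, persistence < 1,
            identical(names(stationary), .synth_stages()),
            abs(sum(stationary) - 1) < 1e-9)
  P <- persistence * diag(6) +
    (1 - persistence) * matrix(stationary, 6, 6, byrow = TRUE)
  dimnames(P) <- list(.synth_stages(), .synth_stages())
  P
}

#' Transition matrix mimicking the wake-dominated composition of
#' overnight PSG databases
#'
#' Independent draws from the stage proportions of the sleep-edf
#' composition table (53\% wake), for exercising class-imbalance
#' behaviour.
#'
#' @return Row-stochastic 6 x 6 matrix.
#' @export
imbalanced_transition <- function() {
  p <- c(W = 8055, S1 = 604, S2 = 3621, S3 = 672, S4 = 627, REM = 1609) / 15188
  P <- matrix(p, 6, 6, byrow = TRUE)
  dimnames(P) <- list(.synth_stages(), .synth_stages())
  P
}

#' Configuration for the synthetic PSG generator
#'
#' @param n_epochs number of 30-s epochs to generate.
#' @param fs sampling rate (Hz).
#' @param epoch_len epoch length (s).
#' @param transition stage-transition matrix (rows sum to 1); see
#'   [default_transition()] and [imbalanced_transition()].
#' @param signal_model stage signatures, see [default_signal_model()].
#' @param channels named character vector mapping channel roles
#'   (`"eog"`, `"eeg"`) to channel labels.
#' @param seed integer seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @return List of class `"synth_config"`.
#' @export
synth_config <- function(n_epochs = 2000L, fs = 100, epoch_len = 30,
                         transition = default_transition(),
                         signal_model = default_signal_model(),
                         channels = c(eog = "EOG horizontal",
                                      eeg = "EEG Fpz-Cz"),
                         seed = 1L) {
  stopifnot(n_epochs >= 1L, fs > 0, epoch_len > 0)
  .check_transition(transition)
  stopifnot(all(names(channels) %in% c("eog", "eeg")))
  structure(
    list(n_epochs = as.integer(n_epochs), fs = fs, epoch_len = epoch_len,
         transition = transition, signal_model = signal_model,
         channels = channels, seed = as.integer(seed)),
    class = "synth_config"
  )
}

.check_transition <- function(P) {
  if (!is.matrix(P) || nrow(P) != 6L || ncol(P) != 6L ||
      any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9)) {
    stop("transition matrix must be 6 x 6, non-negative, rows summing to 1",
         call. = FALSE)
  }
  invisible(P)
}

#' Simulate a hypnogram from a stage-transition Markov chain
#'
#' The chain starts in wake and takes one step per epoch; events are
#' consecutive 30-s (or `epoch_len`) stage annotations.
#'
#' @param cfg a [synth_config()].
#' @return A [hypnogram()] with `cfg$n_epochs` events.
#' @export
generate_hypnogram <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  .check_transition(cfg$transition)
  set.seed(cfg$seed)
  stages <- .synth_stages()
  n <- cfg$n_epochs
  out <- integer(n)
  state <- 1L  # W
  for (i in seq_len(n)) {
    out[i] <- state
    state <- sample.int(6L, 1L, prob = cfg$transition[state, ])
  }
  hypnogram(onset = (seq_len(n) - 1) * cfg$epoch_len,
            duration = rep(cfg$epoch_len, n),
            stage = stages[out])
}

#' Generate one synthetic PSG epoch
#'
#' Sum of the stage's narrow-band sinusoids (frequency jittered and
#' phase randomised per epoch), Hann-windowed transient bursts arriving
#' as a Poisson process, and white noise.
#'
#' @param stage one of the six scoreable stages.
#' @param channel channel role, `"eeg"` or `"eog"`.
#' @param model signal model (see [default_signal_model()]).
#' @param fs sampling rate (Hz).
#' @param epoch_len epoch length (s).
#' @param seed optional seed for a self-contained reproducible draw;
#'   when `NULL` the current RNG stream is used.
#' @return Numeric vector of `fs * epoch_len` samples (microvolts).
#' @export
generate_epoch <- function(stage, channel = c("eeg", "eog"),
                           model = default_signal_model(),
                           fs = 100, epoch_len = 30, seed = NULL) {
  channel <- match.arg(channel)
  stage <- as.character(stage)
  if (!stage %in% .synth_stages()) {
    stop(sprintf("unknown stage '%s'", stage), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  cm <- model[[stage]][[channel]]
  if (is.null(cm)) stop(sprintf("model has no entry for %s/%s", stage, channel),
                        call. = FALSE)
  n <- as.integer(round(fs * epoch_len))
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  oc <- cm$osc
  for (i in seq_len(nrow(oc))) {
    f <- oc$freq[i] + stats::runif(1, -oc$jitter[i], oc$jitter[i])
    x <- x + oc$amp[i] * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
  }
  bu <- cm$bursts
  for (i in seq_len(nrow(bu))) {
    k <- stats::rpois(1, bu$rate[i] * epoch_len)
    for (j in seq_len(k)) {
      onset <- stats::runif(1, 0, epoch_len - bu$dur[i])
      idx <- which(t >= onset & t < onset + bu$dur[i])
      tt <- t[idx] - onset
      win <- 0.5 * (1 - cos(2 * pi * tt / bu$dur[i]))  # Hann envelope
      x[idx] <- x[idx] +
        bu$amp[i] * win * sin(2 * pi * bu$freq[i] * tt + stats::runif(1, 0, 2 * pi))
    }
  }
  if (cm$noise_sd > 0) x <- x + stats::rnorm(n, sd = cm$noise_sd)
  x
}

#' Generate a labelled synthetic PSG dataset
#'
#' Simulates a hypnogram ([generate_hypnogram()]) and per-epoch EOG/EEG
#' signals, optionally writing them to disk as a 16-bit EDF recording
#' plus a per-epoch label file and an EDF+ hypnogram, all readable back
#' through [read_psg()] and [read_hypnogram()].
#'
#' @param cfg a [synth_config()].
#' @param dir optional output directory; when given, writes
#'   `synthetic-psg.edf`, `synthetic-hypnogram.txt` and
#'   `synthetic-hypnogram.edf`.
#' @return An `"epoch_dataset"` (see [segment_epochs()]) with the
#'   hypnogram attached as attribute `"hypnogram"` and, when written,
#'   the file paths as attribute `"files"`.
#' @export
generate_dataset <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  hyp <- generate_hypnogram(cfg)  # seeds the stream with cfg$seed
  labels <- expand_hypnogram(hyp, cfg$epoch_len)
  n <- length(labels)
  spe <- as.integer(round(cfg$fs * cfg$epoch_len))
  roles <- names(cfg$channels)
  x <- array(NA_real_, dim = c(n, length(roles), spe))
  for (i in seq_len(n)) {
    for (j in seq_along(roles)) {
      x[i, j, ] <- generate_epoch(as.character(labels[i]), roles[j],
                                  model = cfg$signal_model,
                                  fs = cfg$fs, epoch_len = cfg$epoch_len)
    }
  }
  ds <- structure(
    list(signals = x, labels = labels, channels = unname(cfg$channels),
         fs = cfg$fs, epoch_len = cfg$epoch_len),
    class = "epoch_dataset"
  )
  attr(ds, "hypnogram") <- hyp
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    signals <- lapply(seq_along(roles), function(j) as.vector(t(x[, j, ])))
    names(signals) <- unname(cfg$channels)
    files <- c(
      psg = file.path(dir, "synthetic-psg.edf"),
      labels = file.path(dir, "synthetic-hypnogram.txt"),
      hypnogram = file.path(dir, "synthetic-hypnogram.edf")
    )
    write_edf(signals, fs = cfg$fs, path = files[["psg"]],
              record_duration = cfg$epoch_len, record_id = "synthetic")
    writeLines(as.character(labels), files[["labels"]])
    write_hypnogram_edf(hyp, files[["hypnogram"]])
    attr(ds, "files") <- files
  }
  ds
}
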