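# Shared fixtures and independent oracles.

# Direct sliding-inner-product convolution oracle:
#   out[f, n] = b[f] + sum_{t, ch} W[f, (t-1)*c + ch] * X[ch, (n-1)*s + t]
# (channel index fastest within a tap, matching the engine layout).
conv1d_oracle <- function(X, W, b, k, s = 1L) {
  c_in <- nrow(X)
  L <- ncol(X)
  Lout <- (L - k) %/% s + 1L
  f <- nrow(W)
  out <- matrix(0, f, Lout)
  for (fi in seq_len(f)) {
    for (n in seq_len(Lout)) {
      acc <- b[fi]
      for (t in seq_len(k)) {
        for (ch in seq_len(c_in)) {
          acc <- acc + W[fi, (t - 1L) * c_in + ch] * X[ch, (n - 1L) * s + t]
        }
      }
      out[fi, n] <- acc
    }
  }
  out
}

# Brute-force per-class TP/FP/FN counter for confusion matrices.
metrics_oracle <- function(cm) {
  k <- nrow(cm)
  out <- data.frame(precision = numeric(k), sensitivity = numeric(k),
                    f1 = numeric(k))
  for (c in seq_len(k)) {
    tp <- cm[c, c]
    fp <- sum(cm[, c]) - tp
    fn <- sum(cm[c, ]) - tp
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    out$precision[c] <- p
    out$sensitivity[c] <- r
    out$f1[c] <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  }
  out
}

# Power in a frequency band [lo, hi] Hz from the raw periodogram.
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  ps <- Mod(stats::fft(x - mean(x)))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- freqs >= lo & freqs <= hi & freqs <= fs / 2
  sum(ps[sel])
}

# A minimal architecture in the same layer vocabulary, for fast engine
# tests that do not need the full 19-layer network.
tiny_spec <- function(input_length = 100L, nb_class = 2L, input_channels = 1L) {
  cnn_spec(
    list(
      sleepcnn:::layer_conv(4, 7, 2),
      sleepcnn:::layer_maxpool(2),
      sleepcnn:::layer_flatten(),
      sleepcnn:::layer_dense(nb_class, activation = "softmax")
    ),
    input_length = input_length, input_channels = input_channels,
    nb_class = nb_class
  )
}

# Two spectrally distinct classes on a short grid, linearly separable in
# practice for the tiny architecture.
toy_classification_data <- function(n = 120L, len = 100L, seed = 42L) {
  set.seed(seed)
  X <- array(0, c(n, 1, len))
  y <- rep(0:1, length.out = n)
  t <- seq_len(len) / len
  for (i in seq_len(n)) {
    f <- if (y[i] == 0) 3 else 12
    X[i, 1, ] <- minmax_01(sin(2 * pi * f * t + runif(1, 0, 6)) + rnorm(len, 0, 0.2))
  }
  list(x = X, y = y)
}
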