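# Fitting interface around the compiled CNN engine.

.act_code <- function(a) switch(a, none = 0L, relu = 1L, softmax = 2L,
                                stop("unknown activation ", a))

# Convert a cnn_spec into the flat op list the engine consumes. The
# dense layer's attached dropout expands into a separate dropout op
# applied after the activation.
.engine_layers <- function(spec) {
  ops <- list()
  for (ly in spec$layers) {
    ops[[length(ops) + 1L]] <- switch(ly$kind,
      conv1d = list(kind = 1L, f = ly$filters, k = ly$kernel, s = ly$stride,
                    act = .act_code(ly$activation)),
      maxpool = list(kind = 2L, pool = ly$pool, s = ly$stride),
      dropout = list(kind = 3L, rate = ly$rate),
      flatten = list(kind = 4L),
      dense = list(kind = 5L, units = ly$units, act = .act_code(ly$activation))
    )
    if (ly$kind == "dense" && ly$dropout > 0) {
      ops[[length(ops) + 1L]] <- list(kind = 3L, rate = ly$dropout)
    }
  }
  ops
}

#' Initialise network weights
#'
#' Glorot (Xavier) uniform initialisation: each weight is drawn from
#' `U(-a, a)` with `a = sqrt(6 / (fan_in + fan_out))`; biases start at
#' zero. Convolution weight matrices are `(filters x channels*kernel)`
#' with channel index fastest within each kernel tap; dense matrices are
#' `(units x n_in)`.
#'
#' @param spec a [cnn_spec()].
#' @param seed integer seed for reproducible draws.
#' @param init `"glorot_uniform"` or `"zero"`.
#' @return List (one element per trainable layer) of `list(W, b)`.
#' @export
init_weights <- function(spec, seed = 1L, init = c("glorot_uniform", "zero")) {
  init <- match.arg(init)
  stopifnot(inherits(spec, "cnn_spec"))
  set.seed(seed)
  ch <- spec$input_channels
  len <- spec$input_length
  out <- list()
  for (ly in spec$layers) {
    if (ly$kind == "conv1d") {
      fan_in <- ch * ly$kernel
      fan_out <- ly$filters * ly$kernel
      a <- sqrt(6 / (fan_in + fan_out))
      W <- matrix(if (init == "zero") 0 else stats::runif(ly$filters * fan_in, -a, a),
                  nrow = ly$filters, ncol = fan_in)
      out[[length(out) + 1L]] <- list(W = W, b = rep(0, ly$filters))
      ch <- ly$filters
      len <- conv_output_length(len, ly$kernel, ly$stride)
    } else if (ly$kind == "maxpool") {
      len <- pool_output_length(len, ly$pool, ly$stride)
    } else if (ly$kind == "flatten") {
      len <- ch * len
      ch <- 1L
    } else if (ly$kind == "dense") {
      a <- sqrt(6 / (len + ly$units))
      W <- matrix(if (init == "zero") 0 else stats::runif(ly$units * len, -a, a),
                  nrow = ly$units, ncol = len)
      out[[length(out) + 1L]] <- list(W = W, b = rep(0, ly$units))
      len <- ly$units
    }
  }
  out
}

.as_input_array <- function(x, spec = NULL) {
  if (inherits(x, "model_input")) x <- unclass(x)
  if (!(is.array(x) && length(dim(x)) == 3L)) {
    stop("`x` must be a 3-d array (n_epochs, n_channels, samples)", call. = FALSE)
  }
  if (!is.null(spec)) {
    if (dim(x)[2] != spec$input_channels || dim(x)[3] != spec$input_length) {
      stop(sprintf(
        "input shape (%d channels x %d samples) does not match the model (%d x %d)",
        dim(x)[2], dim(x)[3], spec$input_channels, spec$input_length),
        call. = FALSE)
    }
  }
  # engine cube layout: (samples, channels, epoch)
  aperm(x, c(3, 2, 1))
}

.encode_labels <- function(y, nb_class, class_names = NULL) {
  if (is.factor(y)) {
    if (is.null(class_names)) class_names <- levels(y)
    y0 <- as.integer(y) - 1L
  } else {
    y0 <- as.integer(y)
    if (any(y0 < 0L)) stop("integer labels must be 0-based class indices", call. = FALSE)
  }
  if (is.null(class_names)) class_names <- as.character(seq_len(nb_class) - 1L)
  if (any(y0 >= nb_class)) {
    stop(sprintf("labels contain class index %d but the model has %d classes",
                 max(y0), nb_class), call. = FALSE)
  }
  list(y0 = y0, class_names = class_names)
}

#' Fit the 1D-CNN sleep-stage classifier
#'
#' Trains the network by mini-batch gradient descent with the Adam
#' optimiser, softmax cross-entropy loss, and a per-update inverse-time
#' learning-rate decay `lr_t = lr / (1 + decay * t)` (`t` counts weight
#' updates). Defaults follow the published training protocol: learning
#' rate 1e-4, decay 3e-3, 100 epochs. Weights are Glorot-uniform
#' initialised from `seed`; the same seed drives batch shuffling and
#' dropout, so identical calls reproduce identical histories.
#'
#' @param x model inputs: a `"model_input"` from [assemble_inputs()] or a
#'   numeric array `(n_epochs, n_channels, samples)` with values in
#'   `[0, 1]`.
#' @param y class labels: a factor (levels define the class order) or
#'   0-based integer class indices. Merge stages with [apply_scheme()]
#'   and drop ambiguous epochs with [filter_ambiguous()] first.
#' @param spec a [cnn_spec()]; defaults to the 19-layer architecture
#'   ([build_model_spec()]) sized from `nb_class` and `dim(x)[2]`.
#' @param nb_class number of classes; defaults to `nlevels(y)` (or
#'   `max(y) + 1` for integer labels).
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param learning_rate initial Adam learning rate.
#' @param decay inverse-time decay coefficient per update.
#' @param validation `NULL` (train on everything), a fraction in (0, 1)
#'   held out at random (seeded), or an integer vector of validation
#'   indices into `x`.
#' @param seed integer seed controlling initialisation, shuffling and
#'   dropout.
#' @param precision `"single"` (the usual deep-learning arithmetic, and
#'   roughly twice as fast) or `"double"`.
#' @param verbose print per-epoch metrics.
#' @return Object of class `"sleep_cnn"`: list with `spec`, `weights`,
#'   `history` (data frame: epoch, loss, accuracy, val_loss,
#'   val_accuracy), `classes`, `config`. Methods: `print`, `summary`,
#'   `predict`, `plot`, `coef`.
#' @seealso [predict.sleep_cnn()], [evaluate()], [split_dataset()]
#' @export
sleep_cnn <- function(x, y, spec = NULL, nb_class = NULL, epochs = 100L,
                      batch_size = 128L, learning_rate = 1e-4, decay = 3e-3,
                      validation = NULL, seed = 1L,
                      precision = c("single", "double"), verbose = FALSE) {
  precision <- match.arg(precision)
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0, decay >= 0)
  if (is.null(nb_class)) {
    nb_class <- if (is.factor(y)) nlevels(y) else max(as.integer(y)) + 1L
  }
  if (is.null(spec)) {
    nch <- if (inherits(x, "model_input") || (is.array(x) && length(dim(x)) == 3L))
      dim(x)[2] else stop("`x` must be a 3-d array", call. = FALSE)
    spec <- build_model_spec(nb_class, nch)
  }
  if (spec$nb_class != nb_class) {
    stop(sprintf("model has %d classes but labels imply %d", spec$nb_class, nb_class),
         call. = FALSE)
  }
  X <- .as_input_array(x, spec)
  n <- dim(X)[3]
  lab <- .encode_labels(y, nb_class)
  if (length(lab$y0) != n) stop("length(y) must match nrow(x)", call. = FALSE)

  if (is.null(validation)) {
    val_idx <- integer()
  } else if (length(validation) == 1L && validation > 0 && validation < 1) {
    set.seed(seed)
    val_idx <- sort(sample.int(n, ceiling(validation * n)))
  } else {
    val_idx <- sort(as.integer(validation))
    stopifnot(all(val_idx >= 1L), all(val_idx <= n))
  }
  train_idx <- setdiff(seq_len(n), val_idx)

  present <- unique(lab$y0[train_idx])
  if (length(present) < nb_class) {
    warning(sprintf("class(es) %s absent from the training labels",
                    paste(setdiff(seq_len(nb_class) - 1L, present), collapse = ", ")))
  }

  weights <- init_weights(spec, seed = seed)
  fit <- cpp_cnn_train(
    .engine_layers(spec), weights, X, lab$y0,
    train_idx - 1L, val_idx - 1L,
    as.integer(epochs), as.integer(batch_size), learning_rate, decay,
    as.numeric(seed), single = precision == "single", verbose = verbose
  )
  history <- data.frame(
    epoch = seq_len(epochs),
    loss = fit$history[, 1], accuracy = fit$history[, 2],
    val_loss = fit$history[, 3], val_accuracy = fit$history[, 4]
  )
  structure(
    list(
      spec = spec, weights = fit$weights, history = history,
      classes = lab$class_names,
      config = list(epochs = epochs, batch_size = batch_size,
                    learning_rate = learning_rate, decay = decay,
                    validation = validation, precision = precision, seed = seed)
    ),
    class = "sleep_cnn"
  )
}

#' Construct a (possibly untrained) network from explicit weights
#'
#' Low-level constructor used for loading saved weights or probing an
#' architecture before training.
#'
#' @param spec a [cnn_spec()].
#' @param weights list of `list(W, b)` per trainable layer (see
#'   [init_weights()]); defaults to Glorot-uniform draws.
#' @param classes optional class names (length `spec$nb_class`).
#' @param seed seed for default initialisation.
#' @return A `"sleep_cnn"` object with empty history.
#' @export
new_sleep_cnn <- function(spec, weights = NULL, classes = NULL, seed = 1L) {
  stopifnot(inherits(spec, "cnn_spec"))
  if (is.null(weights)) weights <- init_weights(spec, seed = seed)
  if (is.null(classes)) classes <- as.character(seq_len(spec$nb_class) - 1L)
  stopifnot(length(classes) == spec$nb_class)
  structure(
    list(spec = spec, weights = weights,
         history = data.frame(epoch = integer(), loss = numeric(),
                              accuracy = numeric(), val_loss = numeric(),
                              val_accuracy = numeric()),
         classes = classes, config = list(seed = seed)),
    class = "sleep_cnn"
  )
}

#' Class probabilities or predicted stages for new epochs
#'
#' Runs the forward pass (dropout inactive) and returns either the
#' softmax class-probability matrix or the argmax class labels.
#'
#' @param object a `"sleep_cnn"` model.
#' @param newdata model inputs (`"model_input"` or 3-d array).
#' @param type `"class"` or `"prob"`.
#' @param precision element type for the forward pass; defaults to the
#'   precision the model was trained with (double for untrained models).
#' @param ... unused.
#' @return For `"prob"`, an `n x nb_class` matrix whose rows sum to 1;
#'   for `"class"`, a factor of predicted class labels.
#' @export
predict.sleep_cnn <- function(object, newdata, type = c("class", "prob"),
                              precision = NULL, ...) {
  type <- match.arg(type)
  if (is.null(precision)) {
    precision <- object$config$precision %||% "double"
  }
  X <- .as_input_array(newdata, object$spec)
  res <- cpp_cnn_forward(.engine_layers(object$spec), object$weights, X,
                         single = precision == "single", shapes = FALSE)
  prob <- t(res$output)
  colnames(prob) <- object$classes
  if (type == "prob") return(prob)
  factor(object$classes[max.col(prob, ties.method = "first")],
         levels = object$classes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-layer activation shapes actually produced by the engine for one
# probe sample; rows of the result are (channels, length) per layer.
# Used to cross-check the closed-form shape inference of cnn_spec().
engine_shapes <- function(spec, weights = NULL, precision = "double") {
  if (is.null(weights)) weights <- init_weights(spec, seed = 1L, init = "zero")
  X <- array(0, dim = c(spec$input_length, spec$input_channels, 1L))
  res <- cpp_cnn_forward(.engine_layers(spec), weights, X,
                         single = precision == "single", shapes = TRUE)
  res$shapes
}

#' @export
print.sleep_cnn <- function(x, ...) {
  trained <- nrow(x$history) > 0L
  cat(sprintf("<sleep_cnn> %d-class model, input %d x %d, %s parameters%s\n",
              x$spec$nb_class, x$spec$input_channels, x$spec$input_length,
              format(sum(x$spec$table$params), big.mark = ","),
              if (trained) sprintf(", trained %d epochs", nrow(x$history))
              else " (untrained)"))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  if (trained) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final training accuracy %.4f%s\n", last$accuracy,
                if (is.finite(last$val_accuracy))
                  sprintf(", validation accuracy %.4f", last$val_accuracy) else ""))
  }
  invisible(x)
}

#' @export
summary.sleep_cnn <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$spec)
  invisible(object)
}

#' @export
coef.sleep_cnn <- function(object, ...) object$weights

#' Plot training history
#'
#' Accuracy (and validation accuracy, when present) per training epoch.
#'
#' @param x a trained `"sleep_cnn"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sleep_cnn <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0L) stop("model has no training history", call. = FALSE)
  graphics::plot(h$epoch, h$accuracy, type = "l", col = "steelblue", lwd = 2,
                 xlab = "epoch", ylab = "accuracy",
                 ylim = range(c(h$accuracy, h$val_accuracy), na.rm = TRUE), ...)
  if (any(is.finite(h$val_accuracy))) {
    graphics::lines(h$epoch, h$val_accuracy, col = "tomato", lwd = 2)
    graphics::legend("bottomright", c("training", "validation"),
                     col = c("steelblue", "tomato"), lwd = 2, bty = "n")
  }
  invisible(x)
}

#' Seeded 70/15/15 train/validation/test split
#'
#' Membership is a single seeded uniform shuffle (not stratified). The
#' validation and test sets take `ceiling(frac * n)` elements each and
#' the training set the remainder, reproducing the published sample
#' counts (e.g. 10,630 / 2,279 / 2,279 for n = 15,188).
#'
#' @param n number of samples (>= 3).
#' @param seed integer seed; the same seed always yields the same split.
#' @param val_frac,test_frac held-out fractions.
#' @return List with sorted integer index vectors `train`, `val`, `test`.
#' @export
#' @examples
#' lengths(split_dataset(15188, seed = 1))
split_dataset <- function(n, seed = 1L, val_frac = 0.15, test_frac = 0.15) {
  if (length(n) != 1L || n < 3L) {
    stop("`n` must be a single integer >= 3", call. = FALSE)
  }
  n <- as.integer(n)
  n_val <- as.integer(ceiling(val_frac * n))
  n_test <- as.integer(ceiling(test_frac * n))
  n_train <- n - n_val - n_test
  if (n_train < 1L) stop("split leaves no training samples", call. = FALSE)
  set.seed(seed)
  perm <- sample.int(n)
  list(
    train = sort(perm[seq_len(n_train)]),
    val = sort(perm[n_train + seq_len(n_val)]),
    test = sort(perm[n_train + n_val + seq_len(n_test)])
  )
}
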