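# Declarative specification of the 19-layer 1D-CNN, with closed-form
# shape and trainable-parameter inference for every layer.

#' Output length of a valid (unpadded) 1D convolution
#'
#' @param L input length in samples.
#' @param k kernel size.
#' @param s stride.
#' @return `floor((L - k) / s) + 1`.
#' @export
#' @examples
#' conv_output_length(3000, 5, 3)  # 999
conv_output_length <- function(L, k, s = 1L) {
  stopifnot(k >= 1L, s >= 1L)
  if (L < k) stop(sprintf("input length %d shorter than kernel %d", L, k), call. = FALSE)
  as.integer((L - k) %/% s + 1L)
}

#' Output length of a 1D max-pooling layer
#'
#' Same valid-window law as [conv_output_length()].
#'
#' @param L input length.
#' @param pool pooling window size.
#' @param s stride (defaults to `pool`).
#' @return `floor((L - pool) / s) + 1`.
#' @export
pool_output_length <- function(L, pool, s = pool) {
  stopifnot(pool >= 1L, s >= 1L)
  if (L < pool) stop(sprintf("input length %d shorter than pool %d", L, pool), call. = FALSE)
  as.integer((L - pool) %/% s + 1L)
}

#' Trainable parameters of a 1D convolution layer
#'
#' `f` filters, each spanning `k` samples of `c_in` input channels, plus
#' one bias per filter: `f * (k * c_in + 1)`.
#'
#' @param c_in input channels.
#' @param f number of filters.
#' @param k kernel size.
#' @return Integer parameter count.
#' @export
#' @examples
#' conv_param_count(1, 64, 5)  # 384
conv_param_count <- function(c_in, f, k) {
  stopifnot(c_in >= 1L, f >= 1L, k >= 1L)
  as.integer(f * (k * c_in + 1L))
}

#' Trainable parameters of a dense layer
#'
#' @param n_in input features.
#' @param units output units.
#' @return `n_in * units + units`.
#' @export
dense_param_count <- function(n_in, units) {
  stopifnot(n_in >= 1L, units >= 1L)
  as.integer(n_in * units + units)
}

# layer constructors for the declarative list
layer_conv <- function(filters, kernel, stride = 1L, activation = "relu") {
  list(kind = "conv1d", filters = as.integer(filters), kernel = as.integer(kernel),
       stride = as.integer(stride), activation = activation)
}
layer_maxpool <- function(pool = 2L, stride = pool) {
  list(kind = "maxpool", pool = as.integer(pool), stride = as.integer(stride))
}
layer_dropout <- function(rate) list(kind = "dropout", rate = rate)
layer_flatten <- function() list(kind = "flatten")
layer_dense <- function(units, activation = "none", dropout = 0) {
  list(kind = "dense", units = as.integer(units), activation = activation,
       dropout = dropout)
}

#' Low-level CNN specification constructor
#'
#' Derives, layer by layer, the output channels, output length and
#' trainable parameter count for an ordered list of layers, starting
#' from a `(input_channels x input_length)` signal. Convolutions and
#' poolings are valid (unpadded). Used by [build_model_spec()]; exposed
#' for building reduced architectures.
#'
#' @param layers list of layer descriptions (see [build_model_spec()]).
#' @param input_length input samples per channel.
#' @param input_channels input channels.
#' @param nb_class number of output classes (the final dense layer's
#'   units).
#' @return Object of class `"cnn_spec"`; its `table` element is a data
#'   frame with one row per layer (kind, config, `out_channels`,
#'   `out_length`, `params`).
#' @export
cnn_spec <- function(layers, input_length, input_channels, nb_class) {
  ch <- as.integer(input_channels)
  len <- as.integer(input_length)
  rows <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    params <- 0L
    switch(ly$kind,
      conv1d = {
        params <- conv_param_count(ch, ly$filters, ly$kernel)
        len <- conv_output_length(len, ly$kernel, ly$stride)
        ch <- ly$filters
      },
      maxpool = {
        len <- pool_output_length(len, ly$pool, ly$stride)
      },
      dropout = {
        stopifnot(ly$rate >= 0, ly$rate < 1)
      },
      flatten = {
        len <- ch * len
        ch <- 1L
      },
      dense = {
        if (ch != 1L) stop("dense layer requires flattened input", call. = FALSE)
        params <- dense_param_count(len, ly$units)
        len <- ly$units
      },
      stop(sprintf("unknown layer kind '%s'", ly$kind), call. = FALSE)
    )
    rows[[i]] <- data.frame(
      layer = i, kind = ly$kind,
      filters = if (ly$kind == "conv1d") ly$filters else NA_integer_,
      kernel = if (ly$kind == "conv1d") ly$kernel else NA_integer_,
      stride = switch(ly$kind, conv1d = ly$stride, maxpool = ly$stride, NA_integer_),
      pool = if (ly$kind == "maxpool") ly$pool else NA_integer_,
      rate = switch(ly$kind, dropout = ly$rate,
                    dense = if (ly$dropout > 0) ly$dropout else NA_real_,
                    NA_real_),
      units = if (ly$kind == "dense") ly$units else NA_integer_,
      activation = switch(ly$kind, conv1d = ly$activation,
                          dense = ly$activation, NA_character_),
      out_channels = ch, out_length = len, params = params
    )
  }
  structure(
    list(layers = layers, input_length = as.integer(input_length),
         input_channels = as.integer(input_channels),
         nb_class = as.integer(nb_class),
         table = do.call(rbind, rows)),
    class = "cnn_spec"
  )
}

#' The 19-layer sleep-staging 1D-CNN specification
#'
#' Builds the fixed 19-layer architecture used for all class counts and
#' signal configurations: seven blocks of strided/unit-stride
#' convolutions with ReLU activations interleaved with width-2
#' max-pooling and dropout, a flatten, a 64-unit ReLU dense layer with
#' dropout 0.2, and a softmax output of `nb_class` units. The input is a
#' `(input_channels x 3000)` scaled 30-s epoch. Layer hyperparameters
#' (in order):
#'
#' conv(64, k5, s3) - conv(128, k3) - pool - drop(0.2) -
#' conv(128, k13) - conv(256, k7) - pool - conv(128, k8) -
#' conv(64, k4) - pool - conv(32, k3) - conv(64, k6) - pool -
#' conv(8, k5) - conv(8, k2) - pool - flatten - dense(64, relu, drop 0.2) -
#' dense(nb_class, softmax)
#'
#' For a single-channel input the derived flatten width is 192 features
#' and the total trainable parameter count is 796,528 + 65 * nb_class.
#'
#' @param nb_class number of sleep classes, in `2:6`.
#' @param input_channels 1 (single EEG or EOG) or 2 (EOG + EEG stacked).
#' @return A [cnn_spec()] with 19 layers. `print()` displays the derived
#'   per-layer table (configuration, trainable parameters, output size).
#' @export
#' @examples
#' spec <- build_model_spec(3, 1)
#' spec$table$params[1]  # 384
#' print(spec)
build_model_spec <- function(nb_class, input_channels = 1L) {
  if (length(nb_class) != 1L || !nb_class %in% 2:6) {
    stop("`nb_class` must be a single integer in 2:6", call. = FALSE)
  }
  if (length(input_channels) != 1L || !input_channels %in% 1:2) {
    stop("`input_channels` must be 1 or 2", call. = FALSE)
  }
  layers <- list(
    layer_conv(64, 5, stride = 3),
    layer_conv(128, 3),
    layer_maxpool(2),
    layer_dropout(0.2),
    layer_conv(128, 13),
    layer_conv(256, 7),
    layer_maxpool(2),
    layer_conv(128, 8),
    layer_conv(64, 4),
    layer_maxpool(2),
    layer_conv(32, 3),
    layer_conv(64, 6),
    layer_maxpool(2),
    layer_conv(8, 5),
    layer_conv(8, 2),
    layer_maxpool(2),
    layer_flatten(),
    layer_dense(64, activation = "relu", dropout = 0.2),
    layer_dense(nb_class, activation = "softmax")
  )
  cnn_spec(layers, input_length = 3000L, input_channels = input_channels,
           nb_class = nb_class)
}

#' @export
print.cnn_spec <- function(x, ...) {
  tb <- x$table
  cfg <- character(nrow(tb))
  for (i in seq_len(nrow(tb))) {
    cfg[i] <- switch(tb$kind[i],
      conv1d = sprintf("%d x %d, stride %d, %s",
                       tb$filters[i], tb$kernel[i], tb$stride[i], tb$activation[i]),
      maxpool = sprintf("pool %d, stride %d", tb$pool[i], tb$stride[i]),
      dropout = sprintf("rate %.1f", tb$rate[i]),
      flatten = "",
      dense = sprintf("%d units, %s%s", tb$units[i], tb$activation[i],
                      if (!is.na(tb$rate[i])) sprintf(", drop %.1f", tb$rate[i]) else "")
    )
  }
  cat(sprintf("<cnn_spec> input %d x %d, %d classes, %s trainable parameters\n",
              x$input_channels, x$input_length, x$nb_class,
              format(sum(tb$params), big.mark = ",")))
  out <- data.frame(
    layer = tb$layer, name = tb$kind, config = cfg,
    params = format(tb$params, big.mark = ","),
    output = sprintf("%d x %d", tb$out_channels, tb$out_length)
  )
  print(out, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' @export
as.data.frame.cnn_spec <- function(x, ...) x$table
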