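test_that("valid-convolution and pooling length formulas", {
  expect_equal(conv_output_length(3000, 5, 3), 999L)
  expect_equal(conv_output_length(999, 3, 1), 997L)
  expect_equal(conv_output_length(10, 10, 1), 1L)
  expect_error(conv_output_length(4, 5, 1), "shorter than kernel")
  expect_equal(pool_output_length(997, 2, 2), 498L)
  expect_equal(pool_output_length(49, 2, 2), 24L)
  expect_equal(pool_output_length(2, 2, 2), 1L)
  expect_error(pool_output_length(1, 2, 2), "shorter than pool")
})

test_that("parameter-count closed forms", {
  expect_equal(conv_param_count(1, 64, 5), 384L)
  expect_equal(conv_param_count(128, 128, 13), 213120L)
  expect_equal(conv_param_count(1, 1, 1), 2L)
  expect_equal(dense_param_count(192, 64), 12352L)
  expect_equal(dense_param_count(64, 3), 195L)
  expect_equal(dense_param_count(1, 1), 2L)
})

test_that("the 19-layer specification derives the published table", {
  spec <- build_model_spec(3, 1)
  tb <- spec$table
  expect_equal(nrow(tb), 19)
  expect_equal(tb$params,
               c(384L, 24704L, 0L, 0L, 213120L, 229632L, 0L, 262272L, 32832L,
                 0L, 6176L, 12352L, 0L, 2568L, 136L, 0L, 0L, 12352L, 195L))
  expect_equal(tb$out_length,
               c(999L, 997L, 498L, 498L, 486L, 480L, 240L, 233L, 230L, 115L,
                 113L, 108L, 54L, 50L, 49L, 24L, 192L, 64L, 3L))
  expect_equal(tb$out_length[tb$kind == "flatten"], 192L)

  # softmax width tracks nb_class; everything upstream is unchanged
  spec5 <- build_model_spec(5, 1)
  expect_equal(spec5$table$params[19], 325L)  # 64*5 + 5
  expect_equal(spec5$table$out_length[1:18], tb$out_length[1:18])

  # two-channel input only widens the first convolution
  spec62 <- build_model_spec(6, 2)
  expect_equal(spec62$table$params[1], 704L)  # 64 * (5*2 + 1)
  expect_equal(spec62$table$out_length, build_model_spec(6, 1)$table$out_length)
  expect_equal(spec62$table$params[-1], build_model_spec(6, 1)$table$params[-1])

  expect_error(build_model_spec(7, 1), "2:6")
  expect_error(build_model_spec(3, 3), "1 or 2")
})

test_that("derived shapes equal the shapes the engine actually produces", {
  for (chans in 1:2) {
    spec <- build_model_spec(4, chans)
    sh <- sleepcnn:::engine_shapes(spec)
    tb <- spec$table
    j <- 0L
    for (i in seq_len(nrow(tb))) {
      j <- j + 1L
      if (tb$kind[i] %in% c("flatten", "dense")) {
        expect_equal(sh[j, 1], tb$out_length[i])
        expect_equal(sh[j, 2], 1L)
      } else {
        expect_equal(sh[j, 1], tb$out_channels[i])
        expect_equal(sh[j, 2], tb$out_length[i])
      }
      # the dense layer's attached dropout adds one engine op
      if (tb$kind[i] == "dense" && !is.na(tb$rate[i])) j <- j + 1L
    }
  }
})

test_that("softmax outputs are probability vectors; zero weights give uniform", {
  spec <- tiny_spec(nb_class = 3)
  m <- new_sleep_cnn(spec, seed = 2)
  x <- array(runif(5 * 100), c(5, 1, 100))
  p <- predict(m, x, type = "prob")
  expect_equal(dim(p), c(5L, 3L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)

  m0 <- new_sleep_cnn(spec, weights = init_weights(spec, init = "zero"))
  p0 <- predict(m0, x, type = "prob")
  expect_equal(as.vector(p0), rep(1 / 3, 15), tolerance = 1e-12)
})

test_that("the convolution follows the sliding inner-product definition", {
  # hand-computed example: S = [1,2,3,4], W = [1,0,-1] -> [-2,-2]
  s1 <- cnn_spec(list(sleepcnn:::layer_conv(1, 3, 1, activation = "none")),
                 input_length = 4, input_channels = 1, nb_class = 2)
  w <- list(list(W = matrix(c(1, 0, -1), 1, 3), b = 0))
  X <- array(c(1, 2, 3, 4), c(1, 1, 4))
  out <- sleepcnn:::cpp_cnn_forward(sleepcnn:::.engine_layers(s1), w,
                                    aperm(X, c(3, 2, 1)), FALSE, FALSE)$output
  expect_equal(as.vector(out), c(-2, -2))
})

test_that("conv layers match the direct summation oracle on random inputs", {
  set.seed(123)
  for (i in 1:100) {
    c_in <- sample(1:3, 1)
    L <- sample(10:40, 1)
    k <- sample(1:min(8, L), 1)
    s <- sample(1:3, 1)
    f <- sample(1:5, 1)
    X <- matrix(rnorm(c_in * L), c_in, L)
    W <- matrix(rnorm(f * c_in * k), f, c_in * k)
    b <- rnorm(f)
    spec <- cnn_spec(list(sleepcnn:::layer_conv(f, k, s, activation = "none")),
                     input_length = L, input_channels = c_in, nb_class = 2)
    Xarr <- array(t(X), c(L, c_in, 1))
    got <- sleepcnn:::cpp_cnn_forward(sleepcnn:::.engine_layers(spec),
                                      list(list(W = W, b = b)),
                                      Xarr, FALSE, FALSE)$output
    want <- conv1d_oracle(X, W, b, k, s)
    # engine output is the (f x Lout) map vectorised column-major
    expect_equal(as.vector(got), as.vector(want), tolerance = 1e-6)
  }
})

test_that("forward is permutation-equivariant over the batch axis", {
  spec <- tiny_spec(nb_class = 2)
  m <- new_sleep_cnn(spec, seed = 9)
  x <- array(runif(6 * 100), c(6, 1, 100))
  p <- predict(m, x, type = "prob")
  perm <- c(4, 1, 6, 2, 5, 3)
  p2 <- predict(m, x[perm, , , drop = FALSE], type = "prob")
  expect_equal(p2, p[perm, ], tolerance = 1e-12)
})

test_that("forward rejects shape mismatches", {
  m <- new_sleep_cnn(tiny_spec(input_length = 100))
  expect_error(predict(m, array(0, c(2, 1, 99))), "does not match")
  expect_error(predict(m, array(0, c(2, 2, 100))), "does not match")
})
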