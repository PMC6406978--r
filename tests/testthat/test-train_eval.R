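test_that("split sizes follow the ceil/remainder law", {
  s <- split_dataset(15188, seed = 1)
  expect_equal(lengths(s), c(train = 10630L, val = 2279L, test = 2279L))
  s2 <- split_dataset(127512, seed = 1)
  expect_equal(lengths(s2), c(train = 89258L, val = 19127L, test = 19127L))
  s3 <- split_dataset(20, seed = 1)
  expect_equal(lengths(s3), c(train = 14L, val = 3L, test = 3L))

  set.seed(31)
  for (n in sample(3:2000, 25)) {
    sp <- split_dataset(n, seed = n)
    expect_equal(length(sp$val), ceiling(0.15 * n))
    expect_equal(length(sp$test), ceiling(0.15 * n))
    expect_equal(length(sp$train), n - 2 * ceiling(0.15 * n))
    all_idx <- c(sp$train, sp$val, sp$test)
    expect_equal(sort(all_idx), seq_len(n))  # disjoint and covering
  }
  expect_error(split_dataset(2), ">= 3")
})

test_that("the split is a deterministic function of the seed", {
  expect_identical(split_dataset(500, seed = 7), split_dataset(500, seed = 7))
  expect_false(identical(split_dataset(500, seed = 7)$train,
                         split_dataset(500, seed = 8)$train))
})

test_that("confusion_metrics agrees with a brute-force TP/FP/FN counter", {
  set.seed(17)
  for (i in 1:30) {
    k <- sample(2:6, 1)
    cm <- matrix(rpois(k * k, 20), k, k)
    got <- confusion_metrics(cm)
    want <- metrics_oracle(cm)
    expect_equal(got$precision, want$precision, tolerance = 1e-12)
    expect_equal(got$sensitivity, want$sensitivity, tolerance = 1e-12)
    expect_equal(got$f1, want$f1, tolerance = 1e-12)
    expect_equal(got$support, rowSums(cm))
  }
  expect_error(confusion_metrics(matrix(1, 2, 3)), "square")
})

test_that("zero-denominator classes yield 0 with a warning", {
  cm <- matrix(c(5, 3, 0, 0), 2)  # nothing predicted as class 2
  expect_warning(m <- confusion_metrics(cm), "zero")
  expect_equal(m$precision[2], 0)
})

test_that("published example metrics reproduce from their counts", {
  # wake: 1196 of 1230 correct -> sensitivity 0.97 (2 dp)
  cm <- rbind(c(1196, 34), c(20, 1300))
  m <- confusion_metrics(cm)
  expect_equal(round(m$sensitivity[1], 2), 0.97)
  # precision 0.54, sensitivity 0.48 -> F1 0.51 (2 dp)
  cm2 <- rbind(c(40, 43), c(34, 1000))
  m2 <- confusion_metrics(cm2)
  expect_equal(round(m2$precision[1], 2), 0.54)
  expect_equal(round(m2$sensitivity[1], 2), 0.48)
  expect_equal(round(m2$f1[1], 2), 0.51)
})

test_that("evaluate builds the confusion matrix by argmax and accuracy by trace", {
  spec <- tiny_spec(nb_class = 2)
  toy <- toy_classification_data(n = 60)
  fit <- sleep_cnn(toy$x, toy$y, spec = spec, epochs = 25, batch_size = 16,
                   learning_rate = 1e-2, seed = 3)
  rep <- evaluate(fit, toy$x, toy$y)
  expect_s3_class(rep, "eval_report")
  expect_equal(sum(rep$confusion), 60)
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / 60)
  expect_equal(unname(rowSums(rep$confusion)), c(30L, 30L))
  expect_error(evaluate(fit, toy$x[0, , , drop = FALSE], integer()), "empty")
})

test_that("an uninformative model predicting one class scores the base rate", {
  spec <- tiny_spec(nb_class = 2)
  m0 <- new_sleep_cnn(spec, weights = init_weights(spec, init = "zero"))
  x <- array(runif(40 * 100), c(40, 1, 100))
  y <- rep(0:1, each = 20)
  rep <- evaluate(m0, x, y)  # uniform probs -> argmax ties to class 0
  expect_equal(rep$accuracy, 0.5)
  expect_equal(unname(colSums(rep$confusion)), c(40L, 0L))
})

test_that("training learns a separable toy problem and is reproducible", {
  spec <- tiny_spec(nb_class = 2)
  toy <- toy_classification_data(n = 120)
  fit <- sleep_cnn(toy$x, toy$y, spec = spec, epochs = 5, batch_size = 16,
                   learning_rate = 1e-2, seed = 11)
  expect_equal(nrow(fit$history), 5)
  expect_gte(fit$history$accuracy[5], 0.9)

  fit2 <- sleep_cnn(toy$x, toy$y, spec = spec, epochs = 5, batch_size = 16,
                    learning_rate = 1e-2, seed = 11)
  expect_identical(fit$history$loss[1], fit2$history$loss[1])
  expect_identical(fit$weights, fit2$weights)

  fit1 <- sleep_cnn(toy$x, toy$y, spec = spec, epochs = 1, seed = 1)
  expect_equal(nrow(fit1$history), 1)
})

test_that("validation indices are monitored, not trained on", {
  spec <- tiny_spec(nb_class = 2)
  toy <- toy_classification_data(n = 80)
  fit <- sleep_cnn(toy$x, toy$y, spec = spec, epochs = 3, batch_size = 16,
                   learning_rate = 1e-2, validation = 61:80, seed = 4)
  expect_true(all(is.finite(fit$history$val_accuracy)))
  # training the same model without the validation rows gives identical
  # weights: the held-out rows do not influence the fit
  fit_no_val <- sleep_cnn(toy$x[1:60, , , drop = FALSE], toy$y[1:60],
                          spec = spec, epochs = 3, batch_size = 16,
                          learning_rate = 1e-2, seed = 4)
  expect_identical(fit$weights, fit_no_val$weights)
})

test_that("a class absent from training triggers a warning but training runs", {
  spec <- tiny_spec(nb_class = 3)
  toy <- toy_classification_data(n = 30)  # labels 0/1 only
  expect_warning(
    fit <- sleep_cnn(toy$x, factor(toy$y, levels = 0:2), spec = spec,
                     epochs = 1, seed = 1),
    "absent"
  )
  expect_equal(nrow(fit$history), 1)
})
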