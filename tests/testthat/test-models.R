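test_that("parameter counts match closed-form formulas", {
  # conv: (k*Cin)*16 + 16; dense1: (Lout*16)*128 + 128; out: 128 + 1
  for (a in c(0L, 3L)) {
    W_s <- 60L
    k <- 4L + a
    l_out <- W_s - k + 1L
    want <- (k * (4L + a)) * 16L + 16L +
      (l_out * 16L) * 128L + 128L + 128L + 1L
    expect_equal(n_params(build_amps_cnn(W_s, a)), want)
  }
  # neighbor MLP 20-20-16-8-1
  expect_equal(n_params(build_neighbor_mlp(20L)),
               20 * 20 + 20 + 20 * 16 + 16 + 16 * 8 + 8 + 8 + 1)
  # combined: conv1 + conv2 + dense(16) on flatten+W_p + dense(8) + dense(1)
  W_s <- 60L; a <- 0L; W_p <- 20L
  l1 <- W_s - 4L + 1L; l2 <- l1 - 16L + 1L
  want <- 4 * 4 * 16 + 16 + 16 * 16 * 16 + 16 +
    (l2 * 16 + W_p) * 16 + 16 + 16 * 8 + 8 + 8 + 1
  expect_equal(n_params(build_combined(W_s, a, W_p)), want)
})

test_that("untrained networks output probabilities and respect shapes", {
  m <- build_amps_cnn(20, 3)
  p <- predict(m, matrix(0, 2, 20 * 7))$prob
  expect_true(all(p > 0 & p < 1))
  expect_error(predict(m, matrix(0, 2, 20 * 4)), "does not match")
  expect_equal(nrow(predict(m, matrix(0, 0, 20 * 7))), 0L)
})

test_that("training learns a separable toy problem and is reproducible", {
  ds <- toy_sequence_dataset(n = 800, W_s = 40, seed = 2)
  sp <- split_80_10_10(ds, seed = 3)
  cfg <- train_config(learning_rate = 0.05, momentum = 0.9, epochs = 8,
                      seed = 4)
  m1 <- train_model(build_amps_cnn(40, 0, seed = 4), sp, cfg)
  expect_gte(max(m1$history$val_acc), 0.95)
  expect_equal(m1$best_epoch, which.max(m1$history$val_acc))
  pred <- predict(m1, sp$test)
  expect_gte(compute_metrics(sp$test$y, pred$call)$accuracy, 0.9)
  # identical seed -> identical history and predictions
  m2 <- train_model(build_amps_cnn(40, 0, seed = 4), sp, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(predict(m2, sp$test)$prob, pred$prob)
})

test_that("prediction threshold is inclusive and batch-size invariant", {
  ds <- toy_sequence_dataset(n = 100, W_s = 20, seed = 6)
  m <- build_amps_cnn(20, 0, seed = 1)
  p1 <- predict(m, ds)$prob
  ns <- asNamespace("methpred")
  p2 <- ns$.nn_predict_prob(m, ds$X, chunk = 7L)
  expect_equal(p1, p2)
  expect_equal(predict(m, ds)$call, as.integer(p1 >= 0.5))
})

test_that("neighbor MLP distinguishes all-low from all-high inputs after training", {
  # neighbors determine the label: label = 1 when levels are high
  withr::with_seed(8, {
    n <- 600
    y <- rep(c(1L, 0L), n / 2)
    V <- matrix(runif(n * 20, 0, 0.3), n) + y * 0.6
  })
  ds <- structure(list(kind = "neighbor", X = V, X2 = NULL, y = y,
                       centers = data.table::data.table(i = seq_len(n)),
                       keys = as.character(seq_len(n)), W_s = NA_integer_,
                       a = NA_integer_, W_p = 20L), class = "meth_dataset")
  sp <- split_80_10_10(ds, seed = 2)
  m <- train_model(build_neighbor_mlp(20, seed = 3), sp,
                   train_config(learning_rate = 0.05, momentum = 0.9,
                                epochs = 10, seed = 3))
  plo <- predict(m, matrix(0, 1, 20))$prob
  phi <- predict(m, matrix(1, 1, 20))$prob
  expect_lt(plo, 0.5)
  expect_gt(phi, 0.5)
})

test_that("combined model accepts zeroed neighbor vectors and trains", {
  withr::with_seed(9, {
    ds <- toy_sequence_dataset(n = 300, W_s = 40, seed = 9)
    cds <- ds
    cds$kind <- "combined"
    cds$X2 <- matrix(runif(300 * 6), 300)
    cds$W_p <- 6L
  })
  sp <- split_80_10_10(cds, seed = 5)
  m <- build_combined(40, 0, W_p = 6, seed = 2)
  p <- predict(m, list_ds <- cds)$prob
  expect_length(p, 300)
  m <- train_model(m, sp, train_config(learning_rate = 0.05, momentum = 0.9,
                                       epochs = 3, seed = 2))
  z <- cds
  z$X2 <- matrix(0, 300, 6)
  expect_true(all(is.finite(predict(m, z)$prob)))
})

test_that("the forest baseline memorizes separable data deterministically", {
  withr::with_seed(1, {
    X <- matrix(rbinom(100 * 30, 1, 0.5), 100)
    y <- X[, 11]
  })
  ds <- structure(list(kind = "sequence", X = X, X2 = NULL, y = y,
                       centers = data.table::data.table(i = 1:100),
                       keys = as.character(1:100), W_s = NA_integer_,
                       a = NA_integer_, W_p = NA_integer_),
                  class = "meth_dataset")
  sp <- split_80_10_10(ds, seed = 4)
  m1 <- train_model(build_random_forest(seed = 7), sp, train_config())
  pred <- predict(m1, sp$train)
  expect_equal(compute_metrics(sp$train$y, pred$call)$accuracy, 1.0)
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))
  m2 <- train_model(build_random_forest(seed = 7), sp, train_config())
  expect_identical(m1$forest$trees, m2$forest$trees)
  # binary-only contract
  ns <- asNamespace("methpred")
  expect_error(ns$rf_fit(matrix(runif(20), 5), c(1, 0, 1, 0, 1)), "binary")
})

test_that("non-finite loss aborts with a diagnostic", {
  ds <- toy_sequence_dataset(n = 100, W_s = 20, seed = 3)
  sp <- split_80_10_10(ds, seed = 1)
  m <- build_amps_cnn(20, 0, seed = 1)
  m$layers[[1]]$W[1, 1] <- NaN # a corrupted weight must abort, not propagate
  expect_error(train_model(m, sp, train_config(epochs = 1, seed = 1)),
               "non-finite")
})

test_that("training on balanced data never lands significantly below chance", {
  ds <- toy_sequence_dataset(n = 300, W_s = 20, seed = 12)
  sp <- split_80_10_10(ds, seed = 13)
  for (seed in 1:5) {
    m <- train_model(build_amps_cnn(20, 0, seed = seed), sp,
                     train_config(learning_rate = 0.05, momentum = 0.9,
                                  epochs = 2, seed = seed))
    # best-epoch validation accuracy on 30 examples: 3 SE below 0.5 is ~0.23
    expect_gte(max(m$history$val_acc), 0.3)
  }
})
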