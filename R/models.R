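# The package's classifiers: sequence(+annotation) CNN, neighbor-level MLP,
# combined network, and a bagged-tree baseline.

#' Training configuration
#'
#' Defaults follow the published training regime: stochastic gradient descent,
#' binary cross-entropy loss, batch size 32, 20 epochs, learning rate 0.001.
#' Momentum is 0 (plain SGD) and configurable.
#'
#' @param batch_size Minibatch size.
#' @param epochs Number of passes over the training partition.
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum (0 = plain SGD).
#' @param seed Integer seed controlling weight initialization, shuffling and
#'   dropout masks; a fixed seed makes training fully reproducible.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 32L, epochs = 20L,
                         learning_rate = 0.001, momentum = 0, seed = 1L) {
  stopifnot(batch_size > 0L, epochs > 0L, learning_rate > 0, momentum >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed)),
            class = "train_config")
}

new_model <- function(kind, layers, spec, concat_after = NULL,
                      input_shift = NULL) {
  structure(list(kind = kind, layers = layers, spec = spec,
                 concat_after = concat_after, input_shift = input_shift,
                 trained = FALSE, history = NULL, best_epoch = NA_integer_,
                 forest = NULL),
            class = "methpred_model")
}

#' @export
print.methpred_model <- function(x, ...) {
  cat(sprintf("methpred_model <%s>%s, %s parameters\n", x$kind,
              if (x$trained) sprintf(" trained (best epoch %d)", x$best_epoch)
              else " (untrained)",
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model A `methpred_model`.
#' @return Integer parameter count (0 for the bagged-tree baseline).
#' @export
n_params <- function(model) {
  if (model$kind == "random_forest") return(0L)
  nn_param_count(model$layers)
}

#' Sequence(+annotation) convolutional classifier
#'
#' Input: a W_s x (4 + a) binary window matrix. Architecture: one 1D
#' convolution across positions with kernel size (4 + a) and 16 output
#' channels (stride 1, no padding), ReLU; flatten; dense layer with 128 nodes,
#' ReLU, dropout 0.5; dense single node whose sigmoid output is interpreted as
#' P(methylated).
#'
#' @param W_s Window size in bp.
#' @param a Number of annotation channels (0 = sequence only, 3 = gene
#'   forward/reverse + repeat).
#' @param seed Seed for weight initialization.
#' @param center_input Subtract a fixed 0.25 from every input bit before the
#'   first layer (an affine recoding that leaves the representable function
#'   class unchanged but markedly improves SGD conditioning on one-hot
#'   inputs; disable for analyses that assume raw 0/1 inputs).
#' @return An untrained `methpred_model` of kind `"amps_cnn"`.
#' @export
build_amps_cnn <- function(W_s, a = 0L, seed = 1L, center_input = TRUE) {
  stopifnot(W_s > 0L, a >= 0L)
  c_in <- 4L + a
  conv <- nn_layer_conv1d(W_s, c_in, 16L, k = c_in)
  layers <- list(conv, nn_layer_relu(),
                 nn_layer_dense(conv$l_out * 16L, 128L),
                 nn_layer_relu(), nn_layer_dropout(0.5),
                 nn_layer_dense(128L, 1L))
  new_model("amps_cnn", nn_init(layers, seed),
            spec = list(W_s = W_s, a = a, init_seed = seed),
            input_shift = if (center_input) list(x = 0.25, x2 = NULL))
}

#' Neighbor-methylation-level classifier
#'
#' A fully connected network over the W_p neighbor methylation levels with
#' layer widths 20, 16, 8 and 1; hidden layers use ReLU and dropout 0.5, the
#' output node a sigmoid.
#'
#' @param W_p Input length (number of neighbor levels; the default 20 matches
#'   the first layer width, other values rescale the first layer).
#' @param widths Layer output widths.
#' @param seed Seed for weight initialization.
#' @return An untrained `methpred_model` of kind `"neighbor_mlp"`.
#' @export
build_neighbor_mlp <- function(W_p = 20L, widths = c(20L, 16L, 8L, 1L),
                               seed = 1L, center_input = TRUE) {
  stopifnot(W_p > 0L, length(widths) >= 2L, widths[length(widths)] == 1L)
  layers <- list()
  d <- W_p
  for (i in seq_along(widths)) {
    layers <- c(layers, list(nn_layer_dense(d, widths[i])))
    if (i < length(widths))
      layers <- c(layers, list(nn_layer_relu(), nn_layer_dropout(0.5)))
    d <- widths[i]
  }
  new_model("neighbor_mlp", nn_init(layers, seed),
            spec = list(W_p = W_p, widths = widths, init_seed = seed),
            input_shift = if (center_input) list(x = 0.5, x2 = NULL))
}

#' Combined sequence + annotation + neighbor classifier
#'
#' The window matrix passes through two 1D convolutions (16 channels each,
#' kernels 4 + a and 16, mirroring the single-conv classifier; this choice is
#' documented as an assumption) with ReLU, then is flattened and concatenated
#' with the W_p neighbor-level vector; the tail is dense layers of widths 16,
#' 8 (ReLU, dropout 0.5) and a sigmoid output node.
#'
#' @inheritParams build_amps_cnn
#' @param W_p Neighbor vector length.
#' @return An untrained `methpred_model` of kind `"combined"`.
#' @export
build_combined <- function(W_s, a = 0L, W_p = 20L, seed = 1L,
                           center_input = TRUE) {
  c_in <- 4L + a
  conv1 <- nn_layer_conv1d(W_s, c_in, 16L, k = c_in)
  conv2 <- nn_layer_conv1d(conv1$l_out, 16L, 16L, k = 16L)
  layers <- list(conv1, nn_layer_relu(), conv2, nn_layer_relu(),
                 nn_layer_dense(conv2$l_out * 16L + W_p, 16L),
                 nn_layer_relu(), nn_layer_dropout(0.5),
                 nn_layer_dense(16L, 8L),
                 nn_layer_relu(), nn_layer_dropout(0.5),
                 nn_layer_dense(8L, 1L))
  new_model("combined", nn_init(layers, seed),
            spec = list(W_s = W_s, a = a, W_p = W_p, init_seed = seed),
            concat_after = 4L,
            input_shift = if (center_input) list(x = 0.25, x2 = 0.5))
}

#' Bagged-tree (random forest) baseline
#'
#' A from-scratch random forest for the flattened binary window encoding:
#' bootstrap-bagged CART trees with Gini splits, 50 trees, unlimited depth,
#' and sqrt(p) features considered per node. Implemented in the package
#' because no forest library is assumed; splits are binary (feature = 0 vs 1),
#' which is exact for the 0/1 window encoding this baseline is specified for.
#'
#' @param n_trees Number of trees.
#' @param mtry Features sampled per node (default floor(sqrt(p))).
#' @param seed Seed making the forest reproducible.
#' @return An untrained `methpred_model` of kind `"random_forest"`.
#' @export
build_random_forest <- function(n_trees = 50L, mtry = NULL, seed = 1L) {
  new_model("random_forest", layers = list(),
            spec = list(n_trees = as.integer(n_trees), mtry = mtry,
                        init_seed = seed))
}

# apply a model's fixed input recoding (subtract a constant)
.shift_inputs <- function(model, X, X2 = NULL) {
  sh <- model$input_shift
  if (!is.null(sh)) {
    if (!is.null(sh$x)) X <- X - sh$x
    if (!is.null(X2) && !is.null(sh$x2)) X2 <- X2 - sh$x2
  }
  list(X = X, X2 = X2)
}

# forward over a dataset in evaluation mode, in chunks
.nn_predict_prob <- function(model, X, X2 = NULL, chunk = 2048L) {
  si <- .shift_inputs(model, X, X2)
  X <- si$X; X2 <- si$X2
  n <- nrow(X)
  p <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    fw <- nn_forward(model$layers, X[s:e, , drop = FALSE],
                     X2 = if (!is.null(X2)) X2[s:e, , drop = FALSE],
                     concat_after = model$concat_after, train = FALSE)
    p[s:e] <- stats::plogis(fw$logit)
  }
  p
}

.ds_inputs <- function(model, ds) {
  if (model$kind == "combined") {
    if (is.null(ds$X2)) stop("combined model needs a combined dataset")
    list(X = ds$X, X2 = ds$X2)
  } else list(X = ds$X, X2 = NULL)
}

#' Train a classifier
#'
#' Networks are trained by plain SGD on binary cross-entropy over the train
#' partition; validation accuracy is recorded after every epoch and the
#' weights from the best epoch (highest validation accuracy, earliest on
#' ties) are returned. The forest baseline is fit in one pass. Training
#' aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param model An untrained `methpred_model`.
#' @param split A `meth_split` from [split_80_10_10()].
#' @param config A [train_config()].
#' @return The trained model, with `$history` (per-epoch mean training loss
#'   and validation accuracy) and `$best_epoch`.
#' @export
train_model <- function(model, split, config = train_config()) {
  stopifnot(inherits(model, "methpred_model"), inherits(split, "meth_split"))
  train <- split$train; val <- split$validation
  if (length(train$y) == 0L || length(val$y) == 0L)
    stop("empty train or validation partition")
  if (model$kind == "random_forest") {
    model$forest <- rf_fit(train$X, train$y,
                           n_trees = model$spec$n_trees,
                           mtry = model$spec$mtry,
                           seed = model$spec$init_seed)
    val_acc <- mean((rf_prob(model$forest, val$X) >= 0.5) == (val$y == 1L))
    model$history <- data.table::data.table(epoch = 1L, train_loss = NA_real_,
                                            val_acc = val_acc)
    model$best_epoch <- 1L
    model$trained <- TRUE
    return(model)
  }
  tin <- .ds_inputs(model, train)
  vin <- .ds_inputs(model, val)
  n <- nrow(tin$X)
  y <- as.numeric(train$y)
  layers <- model$layers
  vel <- NULL
  hist <- data.table::data.table(epoch = integer(), train_loss = numeric(),
                                 val_acc = numeric())
  best <- list(acc = -Inf, layers = layers, epoch = NA_integer_)
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(n)
      loss_sum <- 0
      for (s in seq(1L, n, by = config$batch_size)) {
        b <- idx[s:min(s + config$batch_size - 1L, n)]
        Xb <- tin$X[b, , drop = FALSE]
        X2b <- if (!is.null(tin$X2)) tin$X2[b, , drop = FALSE]
        si <- .shift_inputs(model, Xb, X2b)
        Xb <- si$X; X2b <- si$X2
        fw <- nn_forward(layers, Xb, X2 = X2b,
                         concat_after = model$concat_after, train = TRUE)
        pb <- stats::plogis(fw$logit)
        yb <- y[b]
        eps <- 1e-12
        loss <- -mean(yb * log(pb + eps) + (1 - yb) * log(1 - pb + eps))
        if (!is.finite(loss))
          stop(sprintf("non-finite loss at epoch %d (batch starting %d); ",
                       epoch, s),
               "reduce the learning rate")
        loss_sum <- loss_sum + loss * length(b)
        dlogit <- (pb - yb) / length(b)
        bw <- nn_backward(layers, fw, dlogit, X2 = X2b,
                          concat_after = model$concat_after)
        if (config$momentum > 0) {
          if (is.null(vel)) vel <- lapply(bw$grads, function(g)
            if (is.null(g)) NULL else list(dW = 0 * g$dW, db = 0 * g$db))
          for (i in seq_along(bw$grads)) if (!is.null(bw$grads[[i]])) {
            vel[[i]]$dW <- config$momentum * vel[[i]]$dW + bw$grads[[i]]$dW
            vel[[i]]$db <- config$momentum * vel[[i]]$db + bw$grads[[i]]$db
            bw$grads[[i]] <- vel[[i]]
          }
        }
        layers <- nn_sgd_step(layers, bw$grads, config$learning_rate)
      }
      tmp <- model; tmp$layers <- layers
      vp <- .nn_predict_prob(tmp, vin$X, vin$X2)
      val_acc <- mean((vp >= 0.5) == (val$y == 1L))
      hist <- rbind(hist, data.table::data.table(
        epoch = epoch, train_loss = loss_sum / n, val_acc = val_acc))
      if (val_acc > best$acc) {
        best <- list(acc = val_acc, layers = layers, epoch = epoch)
      }
    }
  })
  model$layers <- best$layers
  model$history <- hist
  model$best_epoch <- best$epoch
  model$trained <- TRUE
  model$train_config <- config
  model
}

#' Predict methylation status
#'
#' Returns P(methylated) and the binary call (probability at least 0.5, the
#' same inclusive threshold used for the level-based call).
#'
#' @param object A trained `methpred_model`.
#' @param newdata A `meth_dataset` (or a plain matrix for network models).
#' @param ... Unused.
#' @return data.table with columns `prob` and `call` (0/1).
#' @export
predict.methpred_model <- function(object, newdata, ...) {
  if (inherits(newdata, "meth_dataset")) {
    if (length(newdata$y) == 0L)
      return(data.table::data.table(prob = numeric(), call = integer()))
    inp <- .ds_inputs(object, newdata)
  } else {
    inp <- list(X = newdata, X2 = NULL)
    if (nrow(inp$X) == 0L)
      return(data.table::data.table(prob = numeric(), call = integer()))
  }
  if (object$kind == "random_forest") {
    if (is.null(object$forest)) stop("untrained forest")
    prob <- rf_prob(object$forest, inp$X)
  } else {
    d_in <- if (object$kind == "neighbor_mlp") object$layers[[1]]$d_in
            else object$layers[[1]]$L * object$layers[[1]]$c_in
    if (ncol(inp$X) != d_in)
      stop("input width ", ncol(inp$X), " does not match model input ", d_in)
    prob <- .nn_predict_prob(object, inp$X, inp$X2)
  }
  data.table::data.table(prob = prob, call = as.integer(prob >= 0.5))
}
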