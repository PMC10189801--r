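# Minimal feed-forward / 1D-convolution neural-network engine.
#
# No deep-learning library is assumed: layers are implemented directly on
# BLAS-backed matrix products. Activations flow through the engine as
# B x D matrices in the channel-major layout of encode_windows(): column
# (c-1)*L + t holds channel c at position t. A 1D convolution is computed by
# an im2col gather (precomputed index vector) followed by a single matrix
# product, so the whole training loop is a handful of GEMMs per batch.
#
# Only what the package's classifiers need is provided: conv1d (stride 1, no
# padding), dense, ReLU, inverted dropout, a sigmoid/binary-cross-entropy
# head, and plain SGD.

nn_layer_conv1d <- function(L, c_in, c_out, k) {
  l_out <- L - k + 1L
  if (l_out < 1L) stop("conv kernel longer than input")
  # input column index for output position t, tap j of channel c, with row
  # order (c-1)*k + j in the weight matrix and t fastest in the gather
  jc <- expand.grid(j = seq_len(k), c = seq_len(c_in))
  idxvec <- as.integer(rep((jc$c - 1L) * L, each = l_out) +
                         rep(jc$j, each = l_out) +
                         rep(seq_len(l_out) - 1L, nrow(jc)))
  list(type = "conv1d", L = L, c_in = c_in, c_out = c_out, k = k,
       l_out = l_out, idxvec = idxvec,
       W = matrix(0, k * c_in, c_out), b = numeric(c_out))
}

nn_layer_dense <- function(d_in, d_out) {
  list(type = "dense", d_in = d_in, d_out = d_out,
       W = matrix(0, d_in, d_out), b = numeric(d_out))
}

nn_layer_relu <- function() list(type = "relu")

nn_layer_dropout <- function(p = 0.5) {
  stopifnot(p >= 0, p < 1)
  list(type = "dropout", p = p)
}

# He-normal initialization for all weight matrices (documented choice; the
# init seed is recorded in the trained model)
nn_init <- function(layers, seed) {
  withr::with_seed(seed, {
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      if (!is.null(l$W)) {
        fan_in <- nrow(l$W)
        layers[[i]]$W <- matrix(stats::rnorm(length(l$W), 0,
                                             sqrt(2 / fan_in)),
                                nrow(l$W), ncol(l$W))
      }
    }
  })
  layers
}

.add_bias <- function(A, b) A + rep(b, each = nrow(A))

# forward pass; X2 is concatenated after layer `concat_after` (combined model)
nn_forward <- function(layers, X, X2 = NULL, concat_after = NULL,
                       train = FALSE) {
  caches <- vector("list", length(layers))
  H <- X
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (!is.null(concat_after) && i == concat_after + 1L) H <- cbind(H, X2)
    if (l$type == "conv1d") {
      B <- nrow(H)
      Z <- H[, l$idxvec, drop = FALSE]
      dim(Z) <- c(B * l$l_out, l$k * l$c_in)
      A <- .add_bias(Z %*% l$W, l$b)
      caches[[i]] <- list(Z = Z, B = B)
      dim(A) <- c(B, l$l_out * l$c_out)
      H <- A
    } else if (l$type == "dense") {
      caches[[i]] <- list(H = H)
      H <- .add_bias(H %*% l$W, l$b)
    } else if (l$type == "relu") {
      mask <- H > 0
      caches[[i]] <- list(mask = mask)
      H <- H * mask
    } else if (l$type == "dropout") {
      if (train) {
        keep <- 1 - l$p
        mask <- (matrix(stats::runif(length(H)), nrow(H)) < keep) / keep
        caches[[i]] <- list(mask = mask)
        H <- H * mask
      } else {
        caches[[i]] <- list(mask = NULL)
      }
    } else stop("unknown layer type ", l$type)
  }
  list(logit = as.numeric(H), caches = caches)
}

# backward pass from d(loss)/d(logit); returns parameter gradients and,
# optionally, the gradient w.r.t. every layer's output (for Grad-CAM)
nn_backward <- function(layers, fw, dlogit, X2 = NULL, concat_after = NULL,
                        record_output_grads = FALSE) {
  n_l <- length(layers)
  grads <- vector("list", n_l)
  dout <- if (record_output_grads) vector("list", n_l)
  dH <- matrix(dlogit, ncol = 1L)
  for (i in rev(seq_len(n_l))) {
    if (record_output_grads) dout[[i]] <- dH # grad w.r.t. output of layer i
    l <- layers[[i]]
    cache <- fw$caches[[i]]
    if (l$type == "dense") {
      grads[[i]] <- list(dW = crossprod(cache$H, dH), db = colSums(dH))
      dH <- tcrossprod(dH, l$W)
    } else if (l$type == "relu") {
      dH <- dH * cache$mask
    } else if (l$type == "dropout") {
      if (!is.null(cache$mask)) dH <- dH * cache$mask
    } else if (l$type == "conv1d") {
      B <- cache$B
      dA <- dH
      dim(dA) <- c(B * l$l_out, l$c_out)
      grads[[i]] <- list(dW = crossprod(cache$Z, dA), db = colSums(dA))
      dZ <- tcrossprod(dA, l$W) # (B*Lout) x (k*Cin)
      dHn <- matrix(0, B, l$L * l$c_in)
      kc <- l$k * l$c_in
      for (jc in seq_len(kc)) {
        cols <- l$idxvec[(jc - 1L) * l$l_out + seq_len(l$l_out)]
        dHn[, cols] <- dHn[, cols] + matrix(dZ[, jc], B, l$l_out)
      }
      dH <- dHn
    }
    if (!is.null(concat_after) && i == concat_after + 1L) {
      keep_cols <- ncol(dH) - ncol(X2)
      dH <- dH[, seq_len(keep_cols), drop = FALSE]
    }
  }
  list(grads = grads, d_input = dH, d_output = dout)
}

nn_sgd_step <- function(layers, grads, lr) {
  for (i in seq_along(layers)) {
    if (!is.null(grads[[i]])) {
      layers[[i]]$W <- layers[[i]]$W - lr * grads[[i]]$dW
      layers[[i]]$b <- layers[[i]]$b - lr * grads[[i]]$db
    }
  }
  layers
}

nn_param_count <- function(layers) {
  sum(vapply(layers, function(l)
    if (is.null(l$W)) 0L else length(l$W) + length(l$b), numeric(1)))
}
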