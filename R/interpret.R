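# Grad-CAM importance scoring of the sequence CNN's input, top-window
# selection, and FASTA export of candidate motif-bearing subsequences.

#' Grad-CAM importance profiles
#'
#' For each example, computes the gradient of the class score (the pre-sigmoid
#' logit, negated when the predicted class is unmethylated) with respect to
#' the post-ReLU activations of the model's last convolutional layer, averages
#' the gradients over positions into per-channel weights, forms the
#' channel-weighted sum of the activation maps, rectifies it (ReLU), and
#' upsamples from convolution resolution to input length by nearest-neighbor
#' repetition.
#'
#' @param model A trained convolutional `methpred_model` (`amps_cnn` or
#'   `combined`).
#' @param X Encoded-window matrix (rows = examples) or a `meth_dataset`.
#' @param X2 Neighbor matrix for combined models.
#' @param chunk Examples per forward/backward batch.
#' @return Matrix n x W_s of nonnegative importance scores.
#' @export
gradcam <- function(model, X, X2 = NULL, chunk = 256L) {
  if (inherits(X, "meth_dataset")) { X2 <- X$X2; X <- X$X }
  si <- .shift_inputs(model, X, X2)
  X <- si$X; X2 <- si$X2
  conv_pos <- which(vapply(model$layers, function(l) l$type == "conv1d",
                           logical(1)))
  if (length(conv_pos) == 0L)
    stop("Grad-CAM requires a convolutional model")
  target <- max(conv_pos) + 1L # the ReLU following the last conv layer
  stopifnot(model$layers[[target]]$type == "relu")
  conv <- model$layers[[max(conv_pos)]]
  l_out <- conv$l_out; c_out <- conv$c_out
  W_s <- model$layers[[min(conv_pos)]]$L
  n <- nrow(X)
  scores <- matrix(0, n, W_s)
  # nearest-neighbor upsampling map from input position to conv position
  upmap <- pmin(pmax(ceiling(seq_len(W_s) * l_out / W_s), 1L), l_out)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    Xb <- X[s:e, , drop = FALSE]
    X2b <- if (!is.null(X2)) X2[s:e, , drop = FALSE]
    fw <- nn_forward(model$layers, Xb, X2 = X2b,
                     concat_after = model$concat_after, train = FALSE)
    pred_meth <- stats::plogis(fw$logit) >= 0.5
    dlogit <- ifelse(pred_meth, 1, -1)
    bw <- nn_backward(model$layers, fw, dlogit, X2 = X2b,
                      concat_after = model$concat_after,
                      record_output_grads = TRUE)
    G <- bw$d_output[[target]]             # grad w.r.t. post-ReLU activations
    # the relu layer caches only its mask; reconstruct the activations from
    # the conv im2col cache
    conv_out <- .add_bias(fw$caches[[max(conv_pos)]]$Z %*% conv$W, conv$b)
    dim(conv_out) <- c(nrow(Xb), l_out * c_out)
    A <- conv_out * fw$caches[[target]]$mask
    Ga <- array(G, c(nrow(Xb), l_out, c_out))
    Aa <- array(A, c(nrow(Xb), l_out, c_out))
    alpha <- apply(Ga, c(1, 3), mean)      # B x Cout channel weights
    cam <- matrix(0, nrow(Xb), l_out)
    for (co in seq_len(c_out)) cam <- cam + Aa[, , co] * alpha[, co]
    cam[cam < 0] <- 0
    scores[s:e, ] <- cam[, upmap, drop = FALSE]
  }
  scores
}

#' Select candidate motif-bearing windows from correctly classified examples
#'
#' Predicts the given dataset, keeps correctly classified examples of each
#' class (up to `n_per_class`, drawn in dataset order; fewer with a message if
#' not enough are available), scores them with [gradcam()], and reports for
#' each the fixed-length window with the highest mean importance (leftmost on
#' ties).
#'
#' @param model Trained convolutional model.
#' @param ds A `meth_dataset` of encoded windows (its `keys` hold the window
#'   sequences).
#' @param n_per_class Maximum examples per true class.
#' @param width Candidate window length (default 50).
#' @return data.table(example, class, window_start (0-based), mean_score,
#'   sequence).
#' @export
select_candidates <- function(model, ds, n_per_class = 10000L, width = 50L) {
  pred <- predict(model, ds)
  out <- list()
  for (cls in c(1L, 0L)) {
    ok <- which(ds$y == cls & pred$call == cls)
    if (length(ok) > n_per_class) ok <- ok[seq_len(n_per_class)]
    if (length(ok) < n_per_class)
      message("only ", length(ok), " correctly classified ",
              if (cls == 1L) "methylated" else "unmethylated",
              " examples available")
    if (length(ok) == 0L) next
    sc <- gradcam(model, ds$X[ok, , drop = FALSE],
                  X2 = if (!is.null(ds$X2)) ds$X2[ok, , drop = FALSE])
    W_s <- ncol(sc)
    if (width > W_s) stop("candidate width exceeds window size")
    # exact per-window sums (a cumsum difference would accumulate rounding
    # error and break the leftmost tie-break on flat profiles)
    sums <- t(apply(sc, 1, function(r)
      stats::filter(r, rep(1, width), sides = 1)[width:W_s]))
    best <- max.col(sums, ties.method = "first")
    out[[length(out) + 1L]] <- data.table::data.table(
      example = ok, class = if (cls == 1L) "methylated" else "unmethylated",
      window_start = best - 1L,
      mean_score = sums[cbind(seq_along(best), best)] / width,
      sequence = substr(ds$keys[ok], best, best + width - 1L))
  }
  data.table::rbindlist(out)
}

#' Export motif candidates as FASTA
#'
#' Headers carry the example id, true class, 0-based window start and mean
#' importance score, separated by `|` (no whitespace, so the file round-trips
#' through [read_fasta()]).
#'
#' @param candidates Output of [select_candidates()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
export_fasta <- function(candidates, path) {
  if (nrow(candidates) == 0L) stop("empty candidate list")
  headers <- sprintf("cand%d|class=%s|window_start=%d|mean_score=%.6g",
                     seq_len(nrow(candidates)), candidates$class,
                     candidates$window_start, candidates$mean_score)
  seqs <- candidates$sequence
  names(seqs) <- headers
  write_fasta(seqs, path)
}
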