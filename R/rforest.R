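# Bagged CART forest on binary features (the flattened 0/1 window encoding).
# Gini-impurity splits of the form "feature == 1"; trees are grown to purity
# (unlimited depth) on a bootstrap sample, with mtry features considered per
# node. Kept deliberately small: this is the baseline, not the contribution.

rf_grow_node <- function(X, y, rows, mtry) {
  n <- length(rows)
  pos <- sum(y[rows])
  if (pos == 0L || pos == n || n < 2L)
    return(list(leaf = TRUE, prob = pos / n))
  feats <- sample.int(ncol(X), mtry)
  Xs <- X[rows, feats, drop = FALSE]
  n1 <- colSums(Xs)
  p1 <- colSums(Xs * y[rows])
  n0 <- n - n1
  p0 <- pos - p1
  valid <- n1 > 0 & n0 > 0
  if (!any(valid)) return(list(leaf = TRUE, prob = pos / n))
  gini <- function(np, nn) ifelse(np + nn > 0,
                                  2 * (np / (np + nn)) * (nn / (np + nn)), 0)
  parent <- gini(pos, n - pos)
  dec <- parent - (n1 * gini(p1, n1 - p1) + n0 * gini(p0, n0 - p0)) / n
  dec[!valid] <- -Inf
  best <- which.max(dec)
  if (dec[best] <= 1e-12) return(list(leaf = TRUE, prob = pos / n))
  f <- feats[best]
  right <- rows[X[rows, f] == 1]
  left <- rows[X[rows, f] == 0]
  list(leaf = FALSE, feat = f,
       left = rf_grow_node(X, y, left, mtry),
       right = rf_grow_node(X, y, right, mtry))
}

rf_fit <- function(X, y, n_trees = 50L, mtry = NULL, seed = 1L) {
  stopifnot(nrow(X) == length(y))
  if (!all(X %in% c(0, 1)))
    stop("the forest baseline expects a binary feature matrix")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  y <- as.integer(y)
  trees <- withr::with_seed(seed, {
    lapply(seq_len(n_trees), function(t) {
      boot <- sample.int(nrow(X), nrow(X), replace = TRUE)
      rf_grow_node(X, y, boot, mtry)
    })
  })
  structure(list(trees = trees, n_trees = n_trees, mtry = mtry,
                 p = ncol(X), seed = seed), class = "methpred_forest")
}

rf_tree_prob <- function(node, X, rows, out) {
  if (node$leaf) {
    out[rows] <- node$prob
    return(out)
  }
  right <- X[rows, node$feat] == 1
  out <- rf_tree_prob(node$right, X, rows[right], out)
  rf_tree_prob(node$left, X, rows[!right], out)
}

# forest class probability: mean of per-tree leaf probabilities
rf_prob <- function(forest, X) {
  if (ncol(X) != forest$p) stop("feature count mismatch")
  probs <- vapply(forest$trees, function(tr)
    rf_tree_prob(tr, X, seq_len(nrow(X)), numeric(nrow(X))),
    numeric(nrow(X)))
  if (nrow(X) == 1L) probs <- matrix(probs, 1L)
  rowMeans(probs)
}
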