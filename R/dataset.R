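# Balanced, context-specific training/validation/test sets of encoded
# sequence windows and neighbor-methylation-level vectors.
#
# Encoded windows are stored one example per row in channel-major layout:
# column (c-1)*W_s + p holds channel c (A,C,G,T, then annotation channels)
# at window position p. The neural-net layers use the same layout.

.onehot_codepoints <- c(65L, 67L, 71L, 84L, 78L) # "ACGTN"

# window code matrix (n x W_s) for centers on one chromosome, oriented 5'->3'
# along the center's strand (minus-strand windows are reverse-complemented)
.window_codes <- function(codes, pos, strand, W_s) {
  half <- W_s %/% 2L
  idx <- outer(pos - half + 1L, 0:(W_s - 1L), "+") # 1-based genome indices
  m <- matrix(codes[idx], nrow = length(pos))
  minus <- strand == "-"
  if (any(minus)) {
    mm <- m[minus, , drop = FALSE]
    m[minus, ] <- matrix(.COMP[mm[, W_s:1, drop = FALSE]], nrow(mm))
  }
  m
}

#' Encode DNA windows (and annotation channels) around candidate cytosines
#'
#' Each center yields a W_s x (4 + a) binary matrix: one-hot DNA columns
#' A,C,G,T (an N base gives an all-zero row) plus, when `tracks` is supplied,
#' the gene-forward, gene-reverse and repeat annotation bits at each window
#' position. Windows span `[pos - W_s/2, pos + W_s/2)`. Minus-strand windows
#' are reverse-complemented so the center cytosine reads C in its own 5'->3'
#' orientation; the row order of annotation bits is reversed accordingly and
#' the two gene channels are swapped (the repeat channel is only reversed).
#' Windows that would run past a chromosome end are rejected, not padded.
#'
#' @param genome A [genome()] object.
#' @param centers data.table with columns chrom, pos (0-based), strand.
#' @param W_s Even window size in bp.
#' @param tracks Optional `annotation_tracks` object (`NULL` disables the
#'   annotation channels, i.e. a = 0).
#' @return List: `X` (kept-example matrix, rows in `centers` order), `keep`
#'   (logical acceptance per input center), `keys` (window sequence strings
#'   of the kept examples), `W_s`, `a`.
#' @export
encode_windows <- function(genome, centers, W_s, tracks = NULL) {
  stopifnot(W_s %% 2L == 0L, W_s > 0L)
  a <- if (is.null(tracks)) 0L else attr(tracks, "a")
  n <- nrow(centers)
  half <- W_s %/% 2L
  lens <- nchar(unclass(genome))
  keep <- unname(centers$pos - half >= 0L &
                   centers$pos + half <= lens[centers$chrom])
  kept <- centers[keep]
  X <- matrix(0, nrow(kept), W_s * (4L + a))
  keys <- character(nrow(kept))
  for (ch in unique(kept$chrom)) {
    rows <- which(kept$chrom == ch)
    codes <- chrom_codes(genome, ch)
    cm <- .window_codes(codes, kept$pos[rows], kept$strand[rows], W_s)
    for (b in 1:4) {
      hit <- which(cm == b)
      if (length(hit))
        X[cbind(rows[(hit - 1L) %% nrow(cm) + 1L],
                (b - 1L) * W_s + (hit - 1L) %/% nrow(cm) + 1L)] <- 1
    }
    keys[rows] <- vapply(seq_len(nrow(cm)), function(i)
      intToUtf8(.onehot_codepoints[cm[i, ]]), character(1))
    if (a > 0L) {
      tr <- tracks[[ch]]
      if (is.null(tr)) stop("no annotation tracks for chromosome ", ch)
      idx <- outer(kept$pos[rows] - half + 1L, 0:(W_s - 1L), "+")
      minus <- kept$strand[rows] == "-"
      fetch <- function(v) {
        m <- matrix(v[idx], length(rows))
        m[minus, ] <- m[minus, W_s:1, drop = FALSE]
        m
      }
      gf <- fetch(tr$gene_fwd); gr <- fetch(tr$gene_rev); rp <- fetch(tr$rep)
      # channel 5: gene on the window's reading strand; channel 6: opposite
      ch5 <- gf; ch5[minus, ] <- gr[minus, , drop = FALSE]
      ch6 <- gr; ch6[minus, ] <- gf[minus, , drop = FALSE]
      X[rows, (4L * W_s + 1L):(5L * W_s)] <- ch5
      X[rows, (5L * W_s + 1L):(6L * W_s)] <- ch6
      X[rows, (6L * W_s + 1L):(7L * W_s)] <- rp
    }
  }
  list(X = X, keep = keep, keys = keys, W_s = W_s, a = a)
}

#' Neighbor methylation-level vectors
#'
#' For each center, takes the W_p/2 covered cytosines (total_reads > 10, any
#' context, either strand) nearest the center on each side, ordered by genomic
#' coordinate (upstream ascending, then downstream ascending), and records
#' their methylation levels. The center itself is excluded. Centers with
#' fewer than W_p/2 covered cytosines on either side are rejected.
#'
#' @param calls A `methylation_calls` object.
#' @param centers data.table with columns chrom, pos.
#' @param W_p Even number of neighbor levels (default 20: 10 per side).
#' @param compute_keys Whether to build deduplication keys (skipped when the
#'   call is only probing eligibility).
#' @return List: `V` (kept-example matrix n x W_p), `keep` (logical per input
#'   center), `keys` (value strings for deduplication), `W_p`.
#' @export
build_neighbor_vectors <- function(calls, centers, W_p = 20L,
                                   compute_keys = TRUE) {
  stopifnot(W_p %% 2L == 0L, W_p > 0L)
  k <- W_p %/% 2L
  covered <- calls[calls$total_reads > 10L, c("chrom", "pos", "level")]
  n <- nrow(centers)
  keep <- logical(n)
  V <- matrix(NA_real_, n, W_p)
  for (ch in unique(centers$chrom)) {
    rows <- which(centers$chrom == ch)
    cv <- covered[covered$chrom == ch]
    o <- order(cv$pos)
    cpos <- cv$pos[o]; clev <- cv$level[o]
    p <- centers$pos[rows]
    n_up <- findInterval(p - 1L, cpos)          # covered positions < p
    dn_start <- findInterval(p, cpos) + 1L      # first covered position > p
    ok <- n_up >= k & dn_start + k - 1L <= length(cpos)
    keep[rows] <- ok
    if (any(ok)) {
      up_idx <- outer(n_up[ok], -(k - 1L):0L, "+")
      dn_idx <- outer(dn_start[ok], 0:(k - 1L), "+")
      V[rows[ok], ] <- cbind(matrix(clev[up_idx], sum(ok)),
                             matrix(clev[dn_idx], sum(ok)))
    }
  }
  V <- V[keep, , drop = FALSE]
  keys <- if (compute_keys && nrow(V))
    apply(V, 1, function(r) paste(format(r, digits = 8), collapse = ","))
  else character(nrow(V))
  list(V = V, keep = keep, keys = keys, W_p = W_p)
}

#' Balanced sampling of candidate cytosines
#'
#' Draws centers uniformly at random without replacement so that the output
#' is exactly label-balanced: for a single context, n/2 methylated and n/2
#' unmethylated; for `"ALL"`, n/6 per (context x label) cell. When any cell
#' holds fewer candidates than its quota, all cell quotas shrink to the
#' minimum availability so the output stays balanced.
#'
#' @param calls A `methylation_calls` object (or any data.table with chrom,
#'   pos, strand, context, status columns).
#' @param context `"CG"`, `"CHG"`, `"CHH"` or `"ALL"`.
#' @param n Requested size (even; divisible by 6 for `"ALL"`).
#' @param seed Integer seed making the draw reproducible.
#' @param eligible Optional logical vector marking usable rows of `calls`
#'   (e.g. window-fits-chromosome), recycled semantics not supported.
#' @return data.table of sampled centers with a binary `label` column
#'   (1 = methylated), shuffled.
#' @export
sample_balanced <- function(calls, context = c("CG", "CHG", "CHH", "ALL"),
                            n, seed = 1L, eligible = NULL) {
  context <- match.arg(context)
  cand <- data.table::as.data.table(calls)
  if (!is.null(eligible)) {
    stopifnot(length(eligible) == nrow(cand))
    cand <- cand[eligible]
  }
  cand <- cand[which(cand$status != "unknown" & !is.na(cand$context))]
  if (context == "ALL") {
    if (n %% 6L != 0L) stop("n must be divisible by 6 for context ALL")
    quota <- n %/% 6L
    cells <- data.table::CJ(context = c("CG", "CHG", "CHH"),
                            status = c("methylated", "unmethylated"))
  } else {
    if (n %% 2L != 0L) stop("n must be even")
    quota <- n %/% 2L
    # which() keeps the filter outside the data.table frame, where the bare
    # name "context" would resolve to the column instead of the argument
    cand <- cand[which(cand$context == context)]
    cells <- data.table::CJ(context = context,
                            status = c("methylated", "unmethylated"))
  }
  avail <- vapply(seq_len(nrow(cells)), function(i)
    sum(cand$context == cells$context[i] & cand$status == cells$status[i]),
    integer(1))
  if (any(avail == 0L))
    stop("no available examples for (", cells$context[which(avail == 0)[1]],
         ", ", cells$status[which(avail == 0)[1]], ")")
  quota <- min(quota, min(avail))
  withr::with_seed(seed, {
    picks <- lapply(seq_len(nrow(cells)), function(i) {
      rows <- which(cand$context == cells$context[i] &
                      cand$status == cells$status[i])
      rows[sample.int(length(rows), quota)]
    })
    out <- cand[unlist(picks)]
    out <- out[sample.int(nrow(out))]
  })
  out$label <- as.integer(out$status == "methylated")
  out
}

# dataset container -----------------------------------------------------------

new_meth_dataset <- function(kind, X, y, centers, keys, X2 = NULL,
                             W_s = NA_integer_, a = NA_integer_,
                             W_p = NA_integer_) {
  structure(list(kind = kind, X = X, X2 = X2, y = as.integer(y),
                 centers = centers, keys = keys, W_s = W_s, a = a, W_p = W_p),
            class = "meth_dataset")
}

#' @export
print.meth_dataset <- function(x, ...) {
  cat(sprintf("meth_dataset (%s): %d examples, label mean %.3f\n",
              x$kind, length(x$y), mean(x$y)))
  invisible(x)
}

#' Subset a dataset by example index
#' @param ds A `meth_dataset`.
#' @param idx Integer indices.
#' @return A `meth_dataset` restricted to `idx`.
#' @export
ds_subset <- function(ds, idx) {
  new_meth_dataset(ds$kind, ds$X[idx, , drop = FALSE], ds$y[idx],
                   ds$centers[idx], ds$keys[idx],
                   X2 = if (!is.null(ds$X2)) ds$X2[idx, , drop = FALSE],
                   W_s = ds$W_s, a = ds$a, W_p = ds$W_p)
}

#' Build a balanced encoded-window dataset
#'
#' Filters candidates to called cytosines whose window fits the chromosome,
#' draws a balanced sample and one-hot encodes it.
#'
#' @inheritParams sample_balanced
#' @inheritParams encode_windows
#' @param tracks `annotation_tracks` or `NULL` (no annotation channels).
#' @return A `meth_dataset` of kind `"sequence"`.
#' @export
build_sequence_dataset <- function(genome, calls, context, n = 500000L,
                                   W_s = 3200L, tracks = NULL, seed = 1L) {
  half <- W_s %/% 2L
  lens <- nchar(unclass(genome))
  eligible <- calls$pos - half >= 0L & calls$pos + half <= lens[calls$chrom]
  centers <- sample_balanced(calls, context, n, seed, eligible = eligible)
  enc <- encode_windows(genome, centers, W_s, tracks)
  stopifnot(all(enc$keep)) # guaranteed by the eligibility filter
  new_meth_dataset("sequence", enc$X, centers$label, centers, enc$keys,
                   W_s = W_s, a = enc$a)
}

#' Build a balanced neighbor-level dataset
#'
#' @inheritParams sample_balanced
#' @inheritParams build_neighbor_vectors
#' @return A `meth_dataset` of kind `"neighbor"` (matrix in `$X`).
#' @export
build_neighbor_dataset <- function(calls, context, n = 50000L, W_p = 20L,
                                   seed = 1L) {
  probe <- build_neighbor_vectors(calls, calls, W_p, compute_keys = FALSE)
  centers <- sample_balanced(calls, context, n, seed, eligible = probe$keep)
  nb <- build_neighbor_vectors(calls, centers, W_p)
  stopifnot(all(nb$keep))
  new_meth_dataset("neighbor", nb$V, centers$label, centers, nb$keys,
                   W_p = W_p)
}

#' Build a balanced combined (window + neighbor) dataset
#'
#' @inheritParams build_sequence_dataset
#' @inheritParams build_neighbor_dataset
#' @return A `meth_dataset` of kind `"combined"` with window matrix `$X` and
#'   neighbor matrix `$X2`.
#' @export
build_combined_dataset <- function(genome, calls, context, n = 50000L,
                                   W_s = 3200L, tracks = NULL, W_p = 20L,
                                   seed = 1L) {
  half <- W_s %/% 2L
  lens <- nchar(unclass(genome))
  fits <- calls$pos - half >= 0L & calls$pos + half <= lens[calls$chrom]
  probe <- build_neighbor_vectors(calls, calls, W_p, compute_keys = FALSE)
  centers <- sample_balanced(calls, context, n, seed,
                             eligible = fits & probe$keep)
  enc <- encode_windows(genome, centers, W_s, tracks)
  nb <- build_neighbor_vectors(calls, centers, W_p)
  stopifnot(all(enc$keep), all(nb$keep))
  new_meth_dataset("combined", enc$X, centers$label, centers, enc$keys,
                   X2 = nb$V, W_s = W_s, a = enc$a, W_p = W_p)
}

#' Split a dataset 80/10/10 into train/validation/test
#'
#' Examples with identical window-sequence keys are deduplicated before
#' splitting so no sequence occurs in more than one partition; the split is
#' stratified by label to preserve the designed balance.
#'
#' @param ds A `meth_dataset`.
#' @param seed Integer seed.
#' @return A `meth_split`: list with `train`, `validation`, `test`
#'   (`meth_dataset`s) and `seed`.
#' @export
split_80_10_10 <- function(ds, seed = 1L) {
  if (length(ds$y) < 10L) stop("need at least 10 examples to split")
  first <- !duplicated(ds$keys)
  ds <- ds_subset(ds, which(first))
  assign_part <- withr::with_seed(seed, {
    part <- character(length(ds$y))
    for (lab in unique(ds$y)) {
      rows <- which(ds$y == lab)
      rows <- rows[sample.int(length(rows))]
      n_l <- length(rows)
      n_val <- round(0.1 * n_l)
      n_test <- round(0.1 * n_l)
      part[rows[seq_len(n_val)]] <- "validation"
      part[rows[n_val + seq_len(n_test)]] <- "test"
      part[rows[(n_val + n_test + 1L):n_l]] <- "train"
    }
    part
  })
  structure(list(train = ds_subset(ds, which(assign_part == "train")),
                 validation = ds_subset(ds, which(assign_part == "validation")),
                 test = ds_subset(ds, which(assign_part == "test")),
                 seed = seed),
            class = "meth_split")
}

#' @export
print.meth_split <- function(x, ...) {
  cat(sprintf("meth_split: train %d / validation %d / test %d (seed %d)\n",
              length(x$train$y), length(x$validation$y), length(x$test$y),
              x$seed))
  invisible(x)
}
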