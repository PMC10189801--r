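# shared helpers for the test suite; fixtures are generated in code

random_seq <- function(n, seed, alphabet = c("A", "C", "G", "T")) {
  withr::with_seed(seed, paste(sample(alphabet, n, TRUE), collapse = ""))
}

# independent brute-force context oracle built on strsplit/chartr only
oracle_context <- function(seq, pos, strand) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  comp <- function(b) chartr("ACGTN", "TGCAN", b)
  get <- function(i, st) {
    if (i < 0 || i >= n) return(NA_character_)
    b <- chars[i + 1]
    if (st == "-") comp(b) else b
  }
  b1 <- if (strand == "+") get(pos + 1, "+") else comp(get(pos - 1, "+"))
  b2 <- if (strand == "+") get(pos + 2, "+") else comp(get(pos - 2, "+"))
  if (is.na(b1) || is.na(b2) || b1 == "N" || b2 == "N") return(NA_character_)
  if (b1 == "G") "CG" else if (b2 == "G") "CHG" else "CHH"
}

# minimal call set from explicit vectors (positions 0-based)
make_calls <- function(genome, chrom, pos, strand, meth, total) {
  ns <- asNamespace("methpred")
  stopifnot(length(unique(chrom)) == 1L)
  ctx <- assign_context(genome, chrom[1], pos, strand)
  ns$new_call_set(data.table::data.table(
    chrom = chrom, pos = as.integer(pos), strand = strand, context = ctx,
    meth_reads = as.integer(meth), total_reads = as.integer(total)), genome)
}

# tiny linearly-separable sequence dataset: label = base A at window center
toy_sequence_dataset <- function(n = 600, W_s = 40, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(0, n, W_s * 4)
    y <- rep(c(1L, 0L), length.out = n)
    for (i in seq_len(n)) {
      codes <- sample(1:4, W_s, TRUE)
      codes[W_s / 2] <- if (y[i] == 1L) 1L else 4L
      for (b in 1:4) X[i, (b - 1) * W_s + which(codes == b)] <- 1
    }
    keys <- apply(X, 1, paste, collapse = "")
    structure(list(kind = "sequence", X = X, X2 = NULL, y = y,
                   centers = data.table::data.table(i = seq_len(n)),
                   keys = keys, W_s = W_s, a = 0L, W_p = NA_integer_),
              class = "meth_dataset")
  })
}
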