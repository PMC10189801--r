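# Genome sequences, sequence context assignment, and Bismark-style
# cytosine-report I/O.

# base codes used throughout: A=1, C=2, G=3, T=4, N=5
.BASES <- c("A", "C", "G", "T", "N")
.COMP <- c(4L, 3L, 2L, 1L, 5L) # complement under the same coding

.byte_code_table <- local({
  tab <- rep(5L, 256)
  for (i in seq_along(.BASES)) {
    tab[utf8ToInt(.BASES[i]) + 1L] <- i          # indexed by byte value + 1
    tab[utf8ToInt(tolower(.BASES[i])) + 1L] <- i
  }
  tab
})

#' Construct a genome object
#'
#' A genome is a named set of chromosome sequences over the alphabet
#' \{A, C, G, T, N\}. Input sequences are uppercased and any other letter
#' (IUPAC ambiguity codes etc.) is normalized to N.
#'
#' @param seqs Named character vector of chromosome sequences.
#' @return An object of class `genome`: a named character vector with an
#'   internal per-chromosome integer-code cache used by window extraction.
#' @export
genome <- function(seqs) {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("all chromosome sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome names")
  if (any(nchar(seqs) == 0L))
    stop("zero-length chromosome sequence")
  seqs <- toupper(seqs)
  seqs <- vapply(seqs, function(s) {
    chartr(paste0(setdiff(strsplit("BDEFHIJKLMOPQRSUVWXYZ", "")[[1]], .BASES),
                  collapse = ""),
           strrep("N", 21L), s)
  }, character(1))
  structure(seqs, class = "genome", codes = new.env(parent = emptyenv()))
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x), "chromosome(s),",
      format(sum(nchar(x)), big.mark = ","), "bp total\n")
  for (nm in names(x)) cat("  ", nm, ": ", nchar(x[[nm]]), " bp\n", sep = "")
  invisible(x)
}

# integer codes (1..5) for one chromosome, cached
chrom_codes <- function(genome, chrom) {
  stopifnot(inherits(genome, "genome"))
  cache <- attr(genome, "codes")
  if (!is.null(cache) && !is.null(cache[[chrom]])) return(cache[[chrom]])
  s <- genome[[chrom]]
  if (is.null(s) || is.na(s)) stop("unknown chromosome: ", chrom)
  codes <- .byte_code_table[as.integer(charToRaw(s)) + 1L]
  if (!is.null(cache)) cache[[chrom]] <- codes
  codes
}

#' Read a FASTA file into a genome object
#'
#' Multi-record and line-wrapped FASTA are supported; lowercase letters are
#' uppercased and non-ACGT letters become N.
#'
#' @param path Path to a FASTA file.
#' @return A [genome()] object.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss)) # keep the id token only
  genome(seqs)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector (or [genome()]) of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::BStringSet(unclass(seqs))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Assign the CG/CHG/CHH context of a cytosine
#'
#' The context of a cytosine is determined by the two bases immediately 3' of
#' it on its own strand (for the minus strand these are the complements of the
#' two reference bases immediately 5' of the position). H denotes A, C or T.
#' If either of the two following bases is N, or lies beyond the chromosome
#' end, the context is undefined and NA is returned.
#'
#' @param genome A [genome()] object.
#' @param chrom Chromosome name (scalar).
#' @param pos 0-based position(s) of the cytosine on the reference.
#' @param strand `"+"` or `"-"`, recycled along `pos`.
#' @return Character vector over \{"CG","CHG","CHH", NA\}.
#' @export
assign_context <- function(genome, chrom, pos, strand) {
  codes <- chrom_codes(genome, chrom)
  n <- length(codes)
  pos <- as.integer(pos)
  if (length(strand) == 1L) strand <- rep(strand, length(pos))
  stopifnot(length(strand) == length(pos))
  if (any(pos < 0L | pos >= n)) stop("position outside chromosome")
  plus <- strand == "+"
  base <- ifelse(plus, codes[pos + 1L], .COMP[codes[pos + 1L]])
  if (any(base != 2L))
    stop("base at position ", pos[which(base != 2L)[1]],
         " strand ", strand[which(base != 2L)[1]], " is not C")
  # two bases 3' of the cytosine on its own strand
  p1 <- ifelse(plus, pos + 1L, pos - 1L)
  p2 <- ifelse(plus, pos + 2L, pos - 2L)
  get3p <- function(p) {
    out <- rep(5L, length(p))
    ok <- p >= 0L & p < n
    out[ok] <- codes[p[ok] + 1L]
    out[ok & !plus] <- .COMP[out[ok & !plus]]
    out[!ok] <- NA_integer_
    out
  }
  b1 <- get3p(p1)
  b2 <- get3p(p2)
  ctx <- rep(NA_character_, length(pos))
  known <- !is.na(b1) & !is.na(b2) & b1 != 5L & b2 != 5L
  ctx[known & b1 == 3L] <- "CG"
  ctx[known & b1 != 3L & b2 == 3L] <- "CHG"
  ctx[known & b1 != 3L & b2 != 3L] <- "CHH"
  ctx
}

#' Binary methylation call from read counts
#'
#' A cytosine covered by 10 or fewer reads has unknown status. Otherwise it is
#' called methylated when its methylation level (methylated reads over total
#' reads) is at least 0.5, and unmethylated below that.
#'
#' @param meth_reads,total_reads Non-negative integer vectors,
#'   `meth_reads <= total_reads`.
#' @param min_coverage Coverage that must be exceeded for a call (default 10,
#'   i.e. at least 11 reads).
#' @return Character vector over \{"methylated","unmethylated","unknown"\}.
#' @export
call_status <- function(meth_reads, total_reads, min_coverage = 10L) {
  if (any(meth_reads < 0) || any(total_reads < 0))
    stop("negative read counts")
  if (any(meth_reads > total_reads))
    stop("meth_reads exceeds total_reads")
  status <- rep("unknown", length(total_reads))
  called <- total_reads > min_coverage
  status[called] <-
    ifelse(meth_reads[called] / total_reads[called] >= 0.5,
           "methylated", "unmethylated")
  status
}

# internal constructor: finalize a calls data.table (level, status, class)
new_call_set <- function(dt, genome) {
  dt <- data.table::as.data.table(dt)
  dt[, level := ifelse(total_reads > 0, meth_reads / total_reads, NA_real_)]
  dt[, status := call_status(meth_reads, total_reads)]
  data.table::setkey(dt, chrom, pos, strand)
  if (anyDuplicated(dt, by = c("chrom", "pos", "strand")))
    stop("duplicate (chrom, pos, strand) records")
  data.table::setattr(dt, "genome", genome)
  data.table::setattr(dt, "class", c("methylation_calls", class(dt)))
  dt
}

#' Read a Bismark-style cytosine report
#'
#' Expected columns: chromosome, 1-based position, strand, count methylated,
#' count unmethylated, context, trinucleotide (last two optional). Positions
#' are converted to 0-based; the context is always recomputed from the genome
#' (a file-stated context is advisory only and discrepancies are reported via
#' a message). Cytosines with undefined context (N in the two downstream
#' bases, or closer than 2 bp to the chromosome end) are dropped with a
#' logged count.
#'
#' @param path Report file (tab- or whitespace-delimited).
#' @param genome A [genome()] object for the same assembly.
#' @return A `methylation_calls` data.table with columns chrom, pos (0-based),
#'   strand, context, meth_reads, total_reads, level, status.
#' @export
read_cytosine_report <- function(path, genome) {
  cols <- c("chrom", "pos1", "strand", "meth_reads", "unmeth_reads",
            "context_stated", "tri")
  dt <- if (file.size(path) == 0)
    data.table::data.table()
  else tryCatch(
    data.table::fread(path, header = FALSE, fill = TRUE,
                      colClasses = list(character = 1)),
    error = function(e) stop("malformed cytosine report: ", conditionMessage(e))
  )
  if (nrow(dt) == 0L)
    return(new_call_set(data.table::data.table(
      chrom = character(), pos = integer(), strand = character(),
      context = character(), meth_reads = integer(), total_reads = integer()),
      genome))
  if (ncol(dt) < 5L) stop("cytosine report needs at least 5 columns")
  data.table::setnames(dt, seq_len(min(ncol(dt), 7L)),
                       cols[seq_len(min(ncol(dt), 7L))])
  bad <- which(is.na(suppressWarnings(as.integer(dt$pos1))) |
                 is.na(suppressWarnings(as.integer(dt$meth_reads))) |
                 is.na(suppressWarnings(as.integer(dt$unmeth_reads))) |
                 !dt$strand %in% c("+", "-"))
  if (length(bad))
    stop("malformed cytosine report line ", bad[1])
  dt[, `:=`(pos1 = as.integer(pos1), meth_reads = as.integer(meth_reads),
            unmeth_reads = as.integer(unmeth_reads))]
  unknown_chrom <- setdiff(unique(dt$chrom), names(genome))
  if (length(unknown_chrom))
    stop("unknown chromosome in report: ", unknown_chrom[1])
  lens <- nchar(unclass(genome))[dt$chrom]
  if (any(dt$pos1 < 1L | dt$pos1 > lens)) {
    i <- which(dt$pos1 < 1L | dt$pos1 > lens)[1]
    stop("position beyond chromosome length at line ", i)
  }
  dt[, pos := pos1 - 1L]
  dt[, context := {
    ctx <- character(.N)
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      ctx[sel] <- assign_context(genome, ch, pos[sel], strand[sel])
    }
    ctx
  }]
  if ("context_stated" %in% names(dt)) {
    mismatch <- sum(!is.na(dt$context) & dt$context_stated != dt$context &
                      dt$context_stated %in% c("CG", "CHG", "CHH"))
    if (mismatch > 0)
      message(mismatch,
              " record(s) had a stated context differing from the genome; ",
              "genome-derived context used")
  }
  dropped <- sum(is.na(dt$context))
  if (dropped > 0)
    message(dropped, " record(s) with undefined context dropped")
  dt <- dt[!is.na(context)]
  new_call_set(dt[, .(chrom, pos, strand, context, meth_reads,
                      total_reads = meth_reads + unmeth_reads)], genome)
}

#' Write a methylation call set as a cytosine report
#'
#' Emits the tab-delimited Bismark-style layout (1-based positions) that
#' [read_cytosine_report()] reads back.
#'
#' @param calls A `methylation_calls` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(calls, path) {
  g <- attr(calls, "genome")
  tri <- vapply(seq_len(nrow(calls)), function(i) {
    codes <- chrom_codes(g, calls$chrom[i])
    p <- calls$pos[i]
    if (calls$strand[i] == "+") {
      idx <- p + c(1L, 2L, 3L)
      b <- ifelse(idx >= 1L & idx <= length(codes), codes[idx], 5L)
    } else {
      idx <- p + c(1L, 0L, -1L)
      b <- .COMP[ifelse(idx >= 1L & idx <= length(codes), codes[idx], 5L)]
    }
    paste(.BASES[b], collapse = "")
  }, character(1))
  out <- data.table::data.table(
    chrom = calls$chrom, pos1 = calls$pos + 1L, strand = calls$strand,
    meth = calls$meth_reads, unmeth = calls$total_reads - calls$meth_reads,
    context = calls$context, tri = tri)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
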