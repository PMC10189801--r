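# Gene-body methylation metaprofiles: 15 bins (5 upstream-flank, 5 gene-body,
# 5 downstream-flank) per context and strand orientation, aggregated over
# genes as a bin-length-weighted average.

# the 15 genomic bin intervals (0-based half-open) of one gene, ordered
# 5'->3' along the gene's strand; body bins use floor division with the
# remainder in the last bin; flank bins are `flank/bins` bp each
gene_bins <- function(start, end, strand, flank = 2000L, bins = 5L) {
  L <- end - start
  if (L < bins) stop("gene shorter than ", bins, " bp cannot form body bins")
  fb <- flank %/% bins
  base <- L %/% bins
  if (strand == "+") {
    up <- lapply(seq_len(bins), function(r)
      c(start - flank + (r - 1L) * fb, start - flank + r * fb))
    body <- lapply(seq_len(bins), function(j)
      c(start + (j - 1L) * base, if (j == bins) end else start + j * base))
    dn <- lapply(seq_len(bins), function(j)
      c(end + (j - 1L) * fb, end + j * fb))
  } else {
    up <- lapply(seq_len(bins), function(r)
      c(end + (bins - r) * fb, end + (bins - r + 1L) * fb))
    body <- lapply(seq_len(bins), function(j)
      c(if (j == bins) start else end - j * base, end - (j - 1L) * base))
    dn <- lapply(seq_len(bins), function(j)
      c(start - j * fb, start - (j - 1L) * fb))
  }
  c(up, body, dn)
}

#' Gene-body methylation metaprofile
#'
#' For every gene, the 2 kb flanks and the gene body are split into 5 bins
#' each (15 bins total, oriented 5'->3' along the gene). In each bin r of gene
#' i, m(r,i) is the ratio of methylated cytosines over all called cytosines of
#' the requested context on the chosen strand orientation, and l(r,i) is the
#' bin length in bp (truncated at chromosome ends). The species-level profile
#' is the weighted average M(r) = sum(m*l) / sum(l) over genes whose bin
#' contains at least one called cytosine; bins with no called cytosine in any
#' gene are reported as NA.
#'
#' The nontemplate orientation is the gene's annotated (mRNA-like) strand;
#' the template orientation is the complementary, transcribed strand.
#'
#' @param calls A `methylation_calls` object.
#' @param genes data.table of gene intervals (chrom, start, end, strand; see
#'   [read_gff3()]); strands must be `+` or `-`.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param flank Flanking-region width in bp (default 2000).
#' @param bins_per_region Bins per region (default 5).
#' @param mode `"status"` counts methylated/called cytosines (the definition
#'   used throughout); `"level"` averages methylation levels instead and is
#'   offered for exploration only.
#' @return data.table(context, orientation, bin, M, genes, total_length)
#'   with orientation in \{"template","nontemplate"\} and bin in 1..15.
#' @export
gene_profile <- function(calls, genes, context = c("CG", "CHG", "CHH"),
                         flank = 2000L, bins_per_region = 5L,
                         mode = c("status", "level")) {
  context <- match.arg(context)
  mode <- match.arg(mode)
  stopifnot(nrow(genes) > 0L, all(genes$strand %in% c("+", "-")))
  g <- attr(calls, "genome")
  lens <- if (!is.null(g)) nchar(unclass(g)) else NULL
  # NB: filter with a plain logical vector built outside the data.table frame
  # ("context" is also a column name and would be captured inside dt[...])
  keep_rows <- which(calls$status != "unknown" & calls$context == context)
  called <- calls[keep_rows]
  # per (chrom, strand): sorted positions with cumulative counts
  index <- list()
  for (ch in unique(called$chrom)) for (st in c("+", "-")) {
    sel <- called[called$chrom == ch & called$strand == st]
    o <- order(sel$pos)
    index[[paste0(ch, st)]] <- list(
      pos = sel$pos[o],
      cum_meth = cumsum(as.numeric(if (mode == "status")
        sel$status[o] == "methylated" else sel$level[o])),
      cum_n = seq_along(o))
  }
  nb <- 3L * bins_per_region
  out <- list()
  for (orient in c("template", "nontemplate")) {
    num <- numeric(nb); den <- numeric(nb); gcount <- integer(nb)
    for (i in seq_len(nrow(genes))) {
      gi <- genes[i]
      bins <- gene_bins(gi$start, gi$end, gi$strand, flank, bins_per_region)
      strand_needed <- if (orient == "nontemplate") gi$strand else
        if (gi$strand == "+") "-" else "+"
      ix <- index[[paste0(gi$chrom, strand_needed)]]
      for (r in seq_len(nb)) {
        s <- max(bins[[r]][1], 0L)
        e <- bins[[r]][2]
        if (!is.null(lens)) e <- min(e, lens[[gi$chrom]])
        l <- e - s
        if (l <= 0L) next
        if (is.null(ix) || length(ix$pos) == 0L) next
        lo <- findInterval(s - 1L, ix$pos) # calls with pos < s
        hi <- findInterval(e - 1L, ix$pos) # calls with pos <= e-1
        n_called <- hi - lo
        if (n_called < 1L) next
        meth <- ix$cum_meth[hi] - if (lo > 0L) ix$cum_meth[lo] else 0
        num[r] <- num[r] + (meth / n_called) * l
        den[r] <- den[r] + l
        gcount[r] <- gcount[r] + 1L
      }
    }
    out[[orient]] <- data.table::data.table(
      context = context, orientation = orient, bin = seq_len(nb),
      M = ifelse(den > 0, num / den, NA_real_),
      genes = gcount, total_length = den)
  }
  data.table::rbindlist(out)
}
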