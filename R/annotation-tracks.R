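# Per-base binary annotation channels (gene forward / gene reverse / repeat)
# built from GFF3, BED or RepeatMasker intervals.

#' Read gene/feature intervals from a GFF3 file
#'
#' Coordinates are normalized to 0-based half-open.
#'
#' @param path GFF3 file.
#' @return A data.table with columns chrom, start (0-based, inclusive),
#'   end (exclusive), strand (`+`, `-` or `.`), feature_type.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = chartr("*", ".", as.character(GenomicRanges::strand(gr))),
    feature_type = as.character(gr$type))
}

#' Read intervals from a BED file
#'
#' BED is already 0-based half-open; columns beyond the sixth are ignored.
#' The feature_type of every interval is `"repeat"` by default (this reader's
#' main use is repeat tracks) but can be overridden.
#'
#' @param path BED file (3+ columns).
#' @param feature_type Type assigned to all intervals.
#' @return A data.table as in [read_gff3()].
#' @export
read_bed <- function(path, feature_type = "repeat") {
  dt <- data.table::fread(path, header = FALSE, fill = TRUE)
  if (ncol(dt) < 3L) stop("BED needs at least 3 columns")
  strand <- if (ncol(dt) >= 6L) as.character(dt[[6]]) else rep(".", nrow(dt))
  strand[!strand %in% c("+", "-")] <- "."
  st <- suppressWarnings(as.integer(dt[[2]]))
  en <- suppressWarnings(as.integer(dt[[3]]))
  if (anyNA(st) || anyNA(en))
    stop("malformed BED coordinates at line ",
         which(is.na(st) | is.na(en))[1])
  data.table::data.table(chrom = as.character(dt[[1]]), start = st, end = en,
                         strand = strand, feature_type = feature_type)
}

#' Read repeat intervals from a RepeatMasker .out file
#'
#' Skips the two header lines and the blank line of the standard format;
#' coordinates (1-based inclusive) are normalized to 0-based half-open.
#'
#' @param path RepeatMasker `.out` file.
#' @return A data.table as in [read_gff3()], feature_type `"repeat"`.
#' @export
read_repeatmasker <- function(path) {
  lines <- readLines(path)
  body <- grep("^\\s*\\d+", lines, value = TRUE)
  if (length(body) == 0L)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  feature_type = character()))
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 9L)) stop("malformed RepeatMasker line ", which(nf < 9L)[1])
  get <- function(i) vapply(fields, `[[`, character(1), i)
  st <- suppressWarnings(as.integer(get(6)))
  en <- suppressWarnings(as.integer(get(7)))
  if (anyNA(st) || anyNA(en))
    stop("malformed RepeatMasker coordinates at line ",
         which(is.na(st) | is.na(en))[1])
  strand <- get(9)
  strand[strand == "C"] <- "-"
  strand[!strand %in% c("+", "-")] <- "."
  data.table::data.table(chrom = get(5), start = st - 1L, end = en,
                         strand = strand, feature_type = "repeat")
}

#' Build binary annotation tracks from feature intervals
#'
#' Produces, per chromosome, three bit vectors used as extra input channels:
#' gene on the forward strand, gene on the reverse strand, and repeats
#' (strand-agnostic). Overlapping intervals are OR-ed. Gene-type intervals
#' with strand "." are symmetric and set both gene channels.
#'
#' @param features data.table of intervals (see [read_gff3()]).
#' @param genome A [genome()] object (defines chromosome lengths).
#' @param gene_types Feature types treated as genes (default `"gene"`;
#'   species-specific sets such as CDS/exon can be supplied).
#' @param repeat_types Feature types treated as repeats.
#' @return An `annotation_tracks` object: per-chromosome list of integer 0/1
#'   vectors `gene_fwd`, `gene_rev`, `rep`, with attribute `a = 3`.
#' @export
build_tracks <- function(features, genome, gene_types = "gene",
                         repeat_types = "repeat") {
  lens <- nchar(unclass(genome))
  tracks <- lapply(lens, function(L)
    list(gene_fwd = integer(L), gene_rev = integer(L), rep = integer(L)))
  names(tracks) <- names(genome)
  if (nrow(features)) {
    unknown <- setdiff(unique(features$chrom), names(genome))
    if (length(unknown)) stop("unknown chromosome: ", unknown[1])
    if (any(features$start < 0L) ||
        any(features$end > lens[features$chrom]) ||
        any(features$start >= features$end))
      stop("interval outside chromosome bounds")
    for (i in seq_len(nrow(features))) {
      f <- features[i]
      span <- (f$start + 1L):f$end
      if (f$feature_type %in% gene_types) {
        if (f$strand %in% c("+", "."))
          tracks[[f$chrom]]$gene_fwd[span] <- 1L
        if (f$strand %in% c("-", "."))
          tracks[[f$chrom]]$gene_rev[span] <- 1L
      } else if (f$feature_type %in% repeat_types) {
        tracks[[f$chrom]]$rep[span] <- 1L
      }
    }
  }
  structure(tracks, class = "annotation_tracks", a = 3L)
}

#' @export
print.annotation_tracks <- function(x, ...) {
  cat("annotation_tracks over", length(x), "chromosome(s), a =",
      attr(x, "a"), "\n")
  for (nm in names(x))
    cat(sprintf("  %s: gene_fwd %d bp, gene_rev %d bp, repeat %d bp\n", nm,
                sum(x[[nm]]$gene_fwd), sum(x[[nm]]$gene_rev),
                sum(x[[nm]]$rep)))
  invisible(x)
}
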