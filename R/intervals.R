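#' Length of the overlap between two genomic intervals
#'
#' Basepair overlap between two intervals. Intervals on different chromosomes
#' do not overlap; this is reported as 0 with a warning rather than an error so
#' that callers iterating over mixed annotation do not abort.
#'
#' @param a,b `GRanges` of length 1 (strand is ignored).
#' @return Integer number of overlapping basepairs (>= 0).
#' @export
#' @examples
#' a <- GenomicRanges::GRanges("I", IRanges::IRanges(1, 10))
#' b <- GenomicRanges::GRanges("I", IRanges::IRanges(6, 15))
#' overlap_length(a, b)  # 5
overlap_length <- function(a, b) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"), length(a) == 1L, length(b) == 1L)
  if (as.character(seqnames(a)) != as.character(seqnames(b))) {
    warning("intervals on different chromosomes; overlap is 0")
    return(0L)
  }
  ov <- min(end(a), end(b)) - max(start(a), start(b)) + 1L
  max(0L, ov)
}

# Total basepairs of `span` covered by the union of `features` (same chrom,
# strand ignored). Used by the repeat-overlap rule and bound-HSE classifier.
covered_bp <- function(span, features) {
  if (length(features) == 0L) return(0L)
  hits <- GenomicRanges::intersect(
    GenomicRanges::reduce(features, ignore.strand = TRUE),
    span, ignore.strand = TRUE)
  sum(width(hits))
}

# Clip a GRanges to [1, seqlength]; adds a logical mcol `edge_clipped`.
# Chromosomes with unknown length are only clipped on the left.
clip_to_chrom <- function(gr, chrom_lengths = NULL) {
  if (length(gr) == 0L) {
    mcols(gr)$edge_clipped <- logical(0)
    return(gr)
  }
  old_start <- start(gr); old_end <- end(gr)
  new_start <- pmax(old_start, 1L)
  new_end <- old_end
  if (!is.null(chrom_lengths)) {
    len <- unname(chrom_lengths[as.character(seqnames(gr))])
    has <- !is.na(len)
    new_end[has] <- pmin(old_end[has], len[has])
  }
  if (any(new_end < new_start))
    stop("interval entirely outside chromosome bounds")
  ranges(gr) <- IRanges(new_start, new_end)
  mcols(gr)$edge_clipped <- new_start != old_start | new_end != old_end
  gr
}

# two-column chrom sizes TSV <-> named integer vector
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, col.names = c("chrom", "length"),
                   colClasses = c("character", "integer"))
  setNames(df$length, df$chrom)
}

write_chrom_sizes <- function(sizes, path) {
  write.table(data.frame(chrom = names(sizes), length = as.integer(sizes)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# plain TSV helpers used by all stage outputs
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, stringsAsFactors = FALSE, ...)
}
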