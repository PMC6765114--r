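#' Gene model container
#'
#' Bundles gene spans, exons and 3'UTR annotation into a single object used by
#' every downstream stage. Coordinates follow the Bioconductor convention
#' (1-based, closed intervals, as in `GRanges`); GTF/BED readers and writers
#' convert to and from the file conventions.
#'
#' @param genes `GRanges` with mcols `gene_id` and `biotype`; one range per
#'   gene covering the span of its exons.
#' @param exons `GRanges` with mcols `gene_id` and `transcript_id`.
#' @param utr3 optional `GRanges` of 3'UTR intervals with mcols `gene_id` and
#'   `transcript_id`.
#' @return An object of class `gene_model_set`.
#' @export
gene_model_set <- function(genes, exons, utr3 = NULL) {
  stopifnot(is(genes, "GRanges"), is(exons, "GRanges"))
  if (is.null(utr3)) utr3 <- GRanges()
  obj <- structure(list(genes = genes, exons = exons, utr3 = utr3),
                   class = "gene_model_set")
  validate_gene_models(obj)
  obj
}

validate_gene_models <- function(x) {
  g <- x$genes; e <- x$exons
  if (length(e) == 0L) return(invisible(x))
  by_tx <- split(seq_along(e), mcols(e)$transcript_id)
  for (idx in by_tx) {
    tx <- e[idx]
    if (length(unique(as.character(seqnames(tx)))) != 1L ||
        length(unique(as.character(strand(tx)))) != 1L)
      stop("exons of transcript ", mcols(tx)$transcript_id[1],
           " span multiple chromosomes or strands")
    o <- order(start(tx))
    if (length(tx) > 1L && any(start(tx)[o][-1] <= end(tx)[o][-length(tx)]))
      stop("overlapping exons in transcript ", mcols(tx)$transcript_id[1])
  }
  ex_gene <- split(seq_along(e), mcols(e)$gene_id)
  gid <- mcols(g)$gene_id
  for (i in seq_along(g)) {
    idx <- ex_gene[[gid[i]]]
    if (is.null(idx)) stop("gene ", gid[i], " has no exons")
    if (start(g)[i] != min(start(e)[idx]) || end(g)[i] != max(end(e)[idx]))
      stop("span of gene ", gid[i], " does not cover its exons")
  }
  invisible(x)
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat("gene_model_set:", length(x$genes), "genes,",
      length(x$exons), "exons,", length(x$utr3), "3'UTR intervals\n")
  invisible(x)
}

#' Read gene models from a GTF file
#'
#' Parses an Ensembl-dialect GTF (1-based, closed coordinates) into a
#' [gene_model_set()]. Only `exon` and `three_prime_utr` features are used;
#' the gene span is derived from the exons. `gene_biotype` defaults to
#' `"protein_coding"` when the attribute is absent.
#'
#' @param path path to a GTF file.
#' @return A `gene_model_set`.
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  for (i in which(body)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop("malformed GTF line ", i, ": expected 9 tab-separated fields, got ",
           length(f))
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e))
      stop("malformed GTF line ", i, ": non-numeric coordinates")
    if (e < s)
      stop("invalid feature on GTF line ", i, ": end (", e, ") < start (", s, ")")
  }
  if (!any(body)) {
    return(gene_model_set(GRanges(gene_id = character(0), biotype = character(0)),
                          GRanges(gene_id = character(0), transcript_id = character(0))))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) stop("GTF contains no exon features")
  if (is.null(ex$gene_id) || anyNA(ex$gene_id))
    stop("exon features must carry a gene_id attribute")
  if (is.null(ex$transcript_id)) ex$transcript_id <- ex$gene_id
  exons <- granges(ex)
  mcols(exons) <- S4Vectors::DataFrame(gene_id = ex$gene_id,
                                       transcript_id = ex$transcript_id)
  bt <- if (!is.null(ex$gene_biotype)) ex$gene_biotype else
    rep(NA_character_, length(ex))
  bt[is.na(bt)] <- "protein_coding"

  gid <- unique(exons$gene_id)
  idx1 <- match(gid, exons$gene_id)
  spans <- unlist(range(split(granges(exons), exons$gene_id)))
  spans <- spans[gid]
  genes <- granges(spans)
  strand(genes) <- strand(exons)[idx1]
  mcols(genes) <- S4Vectors::DataFrame(gene_id = gid, biotype = bt[idx1])

  ut <- gr[gr$type == "three_prime_utr"]
  utr3 <- GRanges()
  if (length(ut) > 0L) {
    utr3 <- granges(ut)
    mcols(utr3) <- S4Vectors::DataFrame(
      gene_id = ut$gene_id,
      transcript_id = if (!is.null(ut$transcript_id)) ut$transcript_id else ut$gene_id)
  }
  gene_model_set(genes, exons, utr3)
}

#' Write gene models as GTF
#'
#' Emits `exon` and `three_prime_utr` rows (1-based, closed coordinates) with
#' `gene_id`, `transcript_id` and `gene_biotype` attributes, re-readable by
#' [read_gene_models()].
#'
#' @param models a `gene_model_set`.
#' @param path output path.
#' @export
write_gene_models <- function(models, path) {
  fmt <- function(gr, type, biotype) {
    if (length(gr) == 0L) return(character(0))
    sprintf('%s\twormhsr\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
            as.character(seqnames(gr)), type, start(gr), end(gr),
            as.character(strand(gr)), mcols(gr)$gene_id,
            mcols(gr)$transcript_id, biotype)
  }
  bt <- setNames(mcols(models$genes)$biotype, mcols(models$genes)$gene_id)
  lines <- c(fmt(models$exons, "exon", unname(bt[mcols(models$exons)$gene_id])),
             fmt(models$utr3, "three_prime_utr",
                 unname(bt[mcols(models$utr3)$gene_id])))
  writeLines(lines, path)
  invisible(path)
}

#' Derive introns from the ordered exons of one transcript
#'
#' Introns are the gaps between consecutive exons after sorting by start.
#' Single-exon transcripts have no introns.
#'
#' @param exons `GRanges` of exons from one transcript (one chrom/strand).
#' @return `GRanges` of introns (possibly empty).
#' @export
derive_introns <- function(exons) {
  stopifnot(is(exons, "GRanges"), length(exons) >= 1L)
  if (length(unique(as.character(seqnames(exons)))) != 1L ||
      length(unique(as.character(strand(exons)))) != 1L)
    stop("exons must share one chromosome and strand")
  o <- order(start(exons))
  s <- start(exons)[o]; e <- end(exons)[o]
  if (length(exons) > 1L && any(s[-1] <= e[-length(e)]))
    stop("overlapping exons; cannot derive introns")
  if (length(exons) == 1L)
    return(GRanges(seqnames = character(0)))
  GRanges(seqnames(exons)[1],
          IRanges(e[-length(e)] + 1L, s[-1] - 1L),
          strand = strand(exons)[1])
}

# Gene-level intronic regions: parts of the gene span covered by no exon of
# the gene. Equals derive_introns() for single-transcript genes; for
# multi-isoform genes a base is intronic only if intronic in every isoform,
# matching the exon-precedence counting rule.
gene_introns <- function(models) {
  gid <- mcols(models$genes)$gene_id
  if (length(gid) == 0L) {
    out <- GRanges(); mcols(out)$gene_id <- character(0)
    return(out)
  }
  ex <- granges(models$exons)
  strand(ex) <- "*"
  exl <- reduce(split(ex, factor(mcols(models$exons)$gene_id, levels = gid)))
  g <- granges(models$genes)
  strand(g) <- "*"
  intr_l <- GenomicRanges::psetdiff(g, exl)
  out <- unlist(intr_l, use.names = FALSE)
  strand(out) <- rep(as.character(strand(models$genes)), lengths(intr_l))
  mcols(out)$gene_id <- rep(gid, lengths(intr_l))
  out
}

# 1-based position of the annotated 5' base of each gene (span start on '+',
# span end on '-').
gene_tss <- function(models) {
  ifelse(as.character(strand(models$genes)) == "-",
         end(models$genes), start(models$genes))
}

#' Intergenic-junction (IJ) windows
#'
#' For each gene, the fixed 21-bp window spanning the annotated 5' start:
#' 11 bases into the gene body (including the 5' base itself) and 10 bases
#' upstream, strand-aware. Readthrough transcription from an upstream gene
#' deposits reads here, so an HS/CTRL imbalance in this window flags a
#' downstream-of-gene (DoG) artifact. Windows running off a chromosome edge
#' are clipped and flagged `edge_clipped`.
#'
#' @param models a `gene_model_set`.
#' @param chrom_lengths optional named integer vector of chromosome lengths.
#' @return `GRanges` with mcols `gene_id` and `edge_clipped`; width 21 unless
#'   clipped.
#' @export
ij_window <- function(models, chrom_lengths = NULL) {
  t5 <- gene_tss(models)
  w <- GRanges(seqnames(models$genes),
               IRanges(t5 - 10L, t5 + 10L),
               strand = strand(models$genes))
  mcols(w)$gene_id <- mcols(models$genes)$gene_id
  clip_to_chrom(w, chrom_lengths)
}

#' Strand-aware promoter windows (1 kb upstream of the annotated start)
#'
#' The promoter excludes the TSS base itself: on `+` the window is the 1000
#' bases below the start; on `-`, the 1000 bases above the 5' end. Clipped at
#' chromosome edges and flagged.
#'
#' @inheritParams ij_window
#' @param promoter_bp window size in bp (default 1000).
#' @return `GRanges` with mcols `gene_id` and `edge_clipped`.
#' @export
promoter_windows <- function(models, promoter_bp = 1000L, chrom_lengths = NULL) {
  p <- flank(models$genes, promoter_bp, start = TRUE)
  p <- granges(p)
  mcols(p)$gene_id <- mcols(models$genes)$gene_id
  clip_to_chrom(p, chrom_lengths)
}
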