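#' Intron retention (IR) score
#'
#' Total normalized intron reads divided by total normalized exon reads for a
#' gene, summed over all samples of both conditions. Elevated when unspliced
#' readthrough or an intron-resident ncRNA contributes reads. Degenerate
#' cases: 0/0 -> 0; x/0 with x > 0 -> +Inf (such genes are removed by the
#' intronic-ncRNA rule).
#'
#' @param intron_norm_total,exon_norm_total non-negative normalized totals.
#' @return Non-negative ratio (possibly `Inf`).
#' @export
ir_score <- function(intron_norm_total, exon_norm_total) {
  if (any(intron_norm_total < 0) || any(exon_norm_total < 0))
    stop("normalized totals must be non-negative")
  ifelse(exon_norm_total == 0,
         ifelse(intron_norm_total == 0, 0, Inf),
         intron_norm_total / exon_norm_total)
}

#' Intergenic-junction (IJ) ratio
#'
#' Normalized HS reads in the 21-bp IJ window divided by normalized CTRL
#' reads, with a pseudocount in numerator and denominator so that an empty
#' window gives a ratio of 1 (never flagged).
#'
#' @param hs_ij_norm,ctrl_ij_norm non-negative per-condition mean normalized
#'   window counts.
#' @param pseudocount added to both terms (default 1 normalized read).
#' @return Positive ratio.
#' @export
ij_ratio <- function(hs_ij_norm, ctrl_ij_norm, pseudocount = 1) {
  if (any(hs_ij_norm < 0) || any(ctrl_ij_norm < 0))
    stop("normalized window counts must be non-negative")
  (hs_ij_norm + pseudocount) / (ctrl_ij_norm + pseudocount)
}

#' Fraction of a gene span covered by repetitive elements
#'
#' The union of repeat intervals intersected with the gene span, divided by
#' the span length; strand is ignored.
#'
#' @param gene_span `GRanges` of length 1.
#' @param repeats `GRanges` of repeat intervals.
#' @return Fraction in `[0, 1]`.
#' @export
repeat_overlap_fraction <- function(gene_span, repeats) {
  stopifnot(is(gene_span, "GRanges"), length(gene_span) == 1L)
  if (width(gene_span) == 0L) stop("zero-length gene span")
  covered_bp(gene_span, repeats) / width(gene_span)
}

#' Per-gene filter metrics for the readthrough false-positive filter
#'
#' Computes, for each gene in `gene_ids`, the IR score (normalized intron /
#' exon totals over all samples), the IJ ratio (per-condition means of
#' normalized 21-bp window counts, pseudocounted) and the repeat-overlap
#' fraction of the gene span.
#'
#' @param gene_ids genes to score (typically the HS-upregulated list).
#' @param ct a `count_table` from [count_features()].
#' @param sf size factors.
#' @param models a `gene_model_set`.
#' @param repeats `GRanges` of repeats (mcol `name`), or NULL.
#' @param windows the IJ windows used in counting (for edge flags); optional.
#' @param pseudocount IJ-ratio pseudocount.
#' @return data.frame: gene_id, ir_score, ij_ratio,
#'   repeat_overlap_fraction, edge_flags.
#' @export
filter_metrics <- function(gene_ids, ct, sf, models, repeats = NULL,
                           windows = NULL, pseudocount = 1) {
  nm <- normalize_counts(ct, sf)
  ctrl <- ct$samples$sample[ct$samples$condition == "CTRL"]
  hs <- ct$samples$sample[ct$samples$condition == "HS"]
  feat <- ct$features
  row_of <- function(g, type) match(paste0(g, ":", type), feat$feature_id)
  ex_tot <- rowSums(nm)[row_of(gene_ids, "exon")]
  in_tot <- rowSums(nm)[row_of(gene_ids, "intron")]
  ij_rows <- row_of(gene_ids, "ij")
  ij_hs <- rowMeans(nm[, hs, drop = FALSE])[ij_rows]
  ij_ctrl <- rowMeans(nm[, ctrl, drop = FALSE])[ij_rows]
  spans <- models$genes[match(gene_ids, mcols(models$genes)$gene_id)]
  rof <- if (is.null(repeats)) rep(0, length(gene_ids)) else
    vapply(seq_along(spans), function(i)
      repeat_overlap_fraction(spans[i], repeats), numeric(1))
  flags <- rep("", length(gene_ids))
  if (!is.null(windows) && !is.null(mcols(windows)$edge_clipped)) {
    cl <- mcols(windows)$gene_id[mcols(windows)$edge_clipped]
    flags[gene_ids %in% cl] <- "edge_clipped"
  }
  data.frame(gene_id = gene_ids,
             ir_score = unname(ir_score(in_tot, ex_tot)),
             ij_ratio = unname(ij_ratio(ij_hs, ij_ctrl, pseudocount)),
             repeat_overlap_fraction = unname(rof),
             edge_flags = flags, stringsAsFactors = FALSE)
}

#' Apply the three-rule false-positive filter to an upregulated gene list
#'
#' Removal rules (all strict inequalities):
#' \itemize{
#' \item `DOG_READTHROUGH`: IR score > `ir_dog` AND IJ ratio > `ij_min`
#'   (readthrough from an upstream induced gene);
#' \item `INTRONIC_NCRNA`: IR score > `ir_ncrna` (intron-resident ncRNA such
#'   as an extended tRNA/snoRNA);
#' \item `REPEAT_OVERLAP`: repeat-overlap fraction > `repeat_frac`.
#' }
#' Reasons accumulate; a gene is removed iff it has at least one reason. The
#' filter applies only to the supplied (upregulated) list.
#'
#' @param upregulated_genes character vector of gene ids.
#' @param reports data.frame from [filter_metrics()] covering every input
#'   gene.
#' @param ir_dog,ij_min,ir_ncrna,repeat_frac thresholds (defaults 0.4, 2, 1,
#'   0.5).
#' @return list with `report` (per-gene verdicts: removed, reasons), `kept`
#'   and `removed` gene-id vectors.
#' @export
apply_filters <- function(upregulated_genes, reports, ir_dog = 0.4,
                          ij_min = 2, ir_ncrna = 1, repeat_frac = 0.5) {
  stopifnot(ir_dog > 0, ij_min > 0, ir_ncrna > 0, repeat_frac > 0)
  miss <- setdiff(upregulated_genes, reports$gene_id)
  if (length(miss) > 0L)
    stop("no filter metrics for gene(s): ", paste(miss, collapse = ", "))
  r <- reports[match(upregulated_genes, reports$gene_id), , drop = FALSE]
  dog <- r$ir_score > ir_dog & r$ij_ratio > ij_min
  ncr <- r$ir_score > ir_ncrna
  rep_ov <- r$repeat_overlap_fraction > repeat_frac
  reasons <- mapply(function(a, b, c_) {
    paste(c("DOG_READTHROUGH", "INTRONIC_NCRNA", "REPEAT_OVERLAP")[c(a, b, c_)],
          collapse = ",")
  }, dog, ncr, rep_ov)
  report <- data.frame(r, removed = dog | ncr | rep_ov, reasons = reasons,
                       row.names = NULL, stringsAsFactors = FALSE)
  list(report = report,
       kept = report$gene_id[!report$removed],
       removed = report$gene_id[report$removed])
}
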