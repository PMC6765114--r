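#' Count reads over exon, intron, IJ-window and repeat features
#'
#' Re-implements the feature-counting step of the filtering pipeline. For
#' each sample:
#' \itemize{
#' \item a read overlapping >= 1 bp of any exon of gene g increments g's
#'   exonic count;
#' \item a read overlapping g's introns but none of g's exons increments g's
#'   intronic count (exon precedence: junction reads are splicing signal, not
#'   retention);
#' \item IJ-window counts increment for any read overlapping the 21-bp window
#'   by >= 1 bp, regardless of gene assignment elsewhere;
#' \item repeat counts increment once per read for the single family with the
#'   largest overlap (ties broken lexicographically by family name).
#' }
#' Counting is strand-aware by default (the read strand must match the
#' feature strand), reflecting stranded library preparations.
#'
#' @param reads named list of `GRanges`, one per sample (BED-like intervals
#'   with strand).
#' @param models a `gene_model_set`.
#' @param windows IJ windows from [ij_window()], or NULL to derive them.
#' @param repeats optional `GRanges` of repeat intervals with mcol `name`
#'   giving the repeat family.
#' @param conditions character vector of condition labels (e.g. "CTRL","HS"),
#'   named by sample; defaults to the text before the last underscore of each
#'   sample name.
#' @param stranded logical; set FALSE for unstranded counting.
#' @return A `count_table`: list with `counts` (integer matrix, features x
#'   samples), `features` (data.frame: feature_id, type, gene_id) and
#'   `samples` (data.frame: sample, condition).
#' @export
count_features <- function(reads, models, windows = NULL, repeats = NULL,
                           conditions = NULL, stranded = TRUE) {
  stopifnot(is.list(reads), !is.null(names(reads)))
  if (is.null(windows)) windows <- ij_window(models)
  if (is.null(conditions))
    conditions <- sub("_[^_]*$", "", names(reads))
  conditions <- unname(conditions[])
  ig <- gene_introns(models)
  gid <- mcols(models$genes)$gene_id
  feat <- data.frame(
    feature_id = c(paste0(gid, ":exon"), paste0(gid, ":intron"),
                   paste0(mcols(windows)$gene_id, ":ij")),
    type = rep(c("exon", "intron", "ij"), c(length(gid), length(gid),
                                            length(windows))),
    gene_id = c(gid, gid, mcols(windows)$gene_id),
    stringsAsFactors = FALSE)
  fams <- character(0)
  if (!is.null(repeats) && length(repeats) > 0L) {
    fams <- sort(unique(mcols(repeats)$name))
    feat <- rbind(feat, data.frame(feature_id = paste0("repeat:", fams),
                                   type = "repeat", gene_id = NA_character_))
  }
  counts <- matrix(0L, nrow(feat), length(reads),
                   dimnames = list(feat$feature_id, names(reads)))
  known <- unique(as.character(seqnames(models$genes)))
  ign <- !stranded
  for (s in names(reads)) {
    rd <- reads[[s]]
    bad <- !(as.character(seqnames(rd)) %in% known)
    if (any(bad)) {
      warning(sum(bad), " read(s) on unknown chromosomes skipped in sample ", s)
      rd <- rd[!bad]
    }
    ng <- length(gid)
    # integer (read, gene) pair keys; dedup once per feature class
    pair_keys <- function(hits, gene_ids) {
      gidx <- match(gene_ids[subjectHits(hits)], gid)
      unique((as.numeric(queryHits(hits)) - 1) * ng + gidx)
    }
    # exonic: unique (read, gene) pairs with any exon overlap
    eh <- findOverlaps(rd, models$exons, ignore.strand = ign)
    ekey <- pair_keys(eh, mcols(models$exons)$gene_id)
    etab <- tabulate((ekey - 1) %% ng + 1, nbins = ng)
    # intronic: intron overlap minus pairs already exonic for that gene
    ih <- findOverlaps(rd, ig, ignore.strand = ign)
    ikey <- setdiff(pair_keys(ih, mcols(ig)$gene_id), ekey)
    itab <- tabulate((ikey - 1) %% ng + 1, nbins = ng)
    # IJ windows: plain >= 1 bp overlap
    wh <- findOverlaps(rd, windows, ignore.strand = ign)
    wgid <- mcols(windows)$gene_id
    widx <- match(wgid[subjectHits(wh)], wgid)
    wtab <- tabulate(
      (unique((as.numeric(queryHits(wh)) - 1) * length(wgid) + widx) - 1) %%
        length(wgid) + 1, nbins = length(wgid))
    col <- c(etab, itab, wtab)
    if (length(fams) > 0L) {
      rh <- findOverlaps(rd, repeats, ignore.strand = ign)
      rtab <- integer(length(fams))
      if (length(rh) > 0L) {
        ovw <- width(pintersect(rd[queryHits(rh)], repeats[subjectHits(rh)],
                                ignore.strand = TRUE))
        df <- data.frame(r = queryHits(rh),
                         fam = mcols(repeats)$name[subjectHits(rh)],
                         w = ovw, stringsAsFactors = FALSE)
        # primary assignment: largest overlap, ties -> lexicographically first
        df <- df[order(df$r, -df$w, df$fam), ]
        df <- df[!duplicated(df$r), ]
        rtab <- as.integer(table(factor(df$fam, levels = fams)))
      }
      col <- c(col, rtab)
    }
    counts[, s] <- col
  }
  structure(list(counts = counts, features = feat,
                 samples = data.frame(sample = names(reads),
                                      condition = conditions,
                                      stringsAsFactors = FALSE)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "features x", ncol(x$counts),
      "samples (", sum(x$features$type == "exon"), "genes )\n")
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' Depth-only normalization: for sample j, the size factor is the median over
#' genes of the ratio of the gene's count to its geometric mean across
#' samples. Genes with a zero count in any sample are excluded from the
#' median. This normalizes to sequencing depth but not to feature length.
#'
#' @param counts integer matrix of exonic gene counts (genes x samples), or a
#'   `count_table` (exon rows are used).
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  if (is(counts, "count_table"))
    counts <- counts$counts[counts$features$type == "exon", , drop = FALSE]
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("negative counts")
  use <- rowSums(counts == 0) == 0
  if (!any(use))
    stop("no gene has nonzero counts in every sample; ",
         "add a pseudocount or filter samples")
  lk <- log(counts[use, , drop = FALSE])
  geo <- rowMeans(lk)
  apply(lk, 2L, function(x) exp(median(x - geo)))
}

#' Depth-normalized counts
#'
#' @param ct a `count_table` or raw matrix.
#' @param sf size factors from [size_factors()] (names must cover samples).
#' @return Numeric matrix of `raw / size_factor` values.
#' @export
normalize_counts <- function(ct, sf) {
  m <- if (is(ct, "count_table")) ct$counts else ct
  stopifnot(all(colnames(m) %in% names(sf)), all(sf > 0))
  sweep(m, 2L, sf[colnames(m)], "/")
}

#' Fold changes and baseMean from normalized counts
#'
#' `baseMean` is the mean of depth-normalized counts over all samples;
#' `log2fc` is `log2((mean HS + pc) / (mean CTRL + pc))` with pseudocount
#' `pc` guarding zero denominators.
#'
#' @param ct a `count_table`.
#' @param sf size factors.
#' @param ctrl,hs sample names of the two conditions; default: samples whose
#'   condition label is "CTRL" / "HS".
#' @param pseudocount added to both condition means (normalized units).
#' @return data.frame: feature_id, type, gene_id, baseMean, log2fc.
#' @export
fold_changes <- function(ct, sf, ctrl = NULL, hs = NULL, pseudocount = 1) {
  stopifnot(is(ct, "count_table"))
  if (is.null(ctrl)) ctrl <- ct$samples$sample[ct$samples$condition == "CTRL"]
  if (is.null(hs)) hs <- ct$samples$sample[ct$samples$condition == "HS"]
  stopifnot(length(ctrl) >= 1L, length(hs) >= 1L)
  nm <- normalize_counts(ct, sf)
  base_mean <- rowMeans(nm[, c(ctrl, hs), drop = FALSE])
  mc <- rowMeans(nm[, ctrl, drop = FALSE])
  mh <- rowMeans(nm[, hs, drop = FALSE])
  data.frame(ct$features,
             baseMean = base_mean,
             log2fc = log2((mh + pseudocount) / (mc + pseudocount)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify differentially expressed features by fold change and baseMean
#'
#' `up`: log2fc >= log2(fc_threshold) and baseMean >= basemean_min (both
#' inclusive); `down` is symmetric with log2fc <= -log2(fc_threshold).
#' No significance testing is performed: this reproduces the fold-change +
#' baseMean component of the published thresholds only.
#'
#' @param records data.frame from [fold_changes()].
#' @param fc_threshold linear fold-change threshold (default 2).
#' @param basemean_min minimum baseMean (e.g. 50 for gene classes, 100 for
#'   repeat families).
#' @param direction "up" or "down".
#' @return Character vector of feature_ids.
#' @export
classify_de <- function(records, fc_threshold = 2, basemean_min = 50,
                        direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(fc_threshold > 0, basemean_min > 0)
  lt <- log2(fc_threshold)
  keep <- if (direction == "up") records$log2fc >= lt else records$log2fc <= -lt
  records$feature_id[keep & records$baseMean >= basemean_min]
}
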