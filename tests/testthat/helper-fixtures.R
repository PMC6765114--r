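suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

# build a gene_model_set from a list of gene specs:
#   list(id=, chrom=, strand=, exons=list(c(s,e),...), utr=c(s,e) or NULL)
toy_models <- function(specs) {
  exs <- list(); gns <- list(); uts <- list()
  for (sp in specs) {
    em <- do.call(rbind, sp$exons)
    ex <- GRanges(sp$chrom, IRanges(em[, 1], em[, 2]), strand = sp$strand)
    mcols(ex)$gene_id <- sp$id
    mcols(ex)$transcript_id <- if (!is.null(sp$tx)) sp$tx else
      paste0(sp$id, ".t1")
    exs[[length(exs) + 1L]] <- ex
    g <- GRanges(sp$chrom, IRanges(min(em[, 1]), max(em[, 2])),
                 strand = sp$strand)
    mcols(g)$gene_id <- sp$id
    mcols(g)$biotype <- if (!is.null(sp$biotype)) sp$biotype else
      "protein_coding"
    gns[[length(gns) + 1L]] <- g
    if (!is.null(sp$utr)) {
      u <- GRanges(sp$chrom, IRanges(sp$utr[1], sp$utr[2]),
                   strand = sp$strand)
      mcols(u)$gene_id <- sp$id
      mcols(u)$transcript_id <- paste0(sp$id, ".t1")
      uts[[length(uts) + 1L]] <- u
    }
  }
  gene_model_set(do.call(c, gns), do.call(c, exs),
                 if (length(uts)) do.call(c, uts) else NULL)
}

# independent brute-force per-read counting oracle (plain closed-interval
# arithmetic, no findOverlaps): rows = c(gene:exon, gene:intron, gene:ij)
oracle_counts <- function(reads_gr, models, windows, stranded = TRUE) {
  gid <- mcols(models$genes)$gene_id
  rs <- start(reads_gr); re <- end(reads_gr)
  rc <- as.character(seqnames(reads_gr)); rstr <- as.character(strand(reads_gr))
  # plain per-gene structures, extracted once
  exg <- mcols(models$exons)$gene_id
  exs <- start(models$exons); exe <- end(models$exons)
  genes <- lapply(seq_along(gid), function(i) {
    k <- which(exg == gid[i])
    o <- k[order(exs[k])]
    s <- exs[o]; e <- exe[o]
    is_ <- if (length(s) > 1) e[-length(e)] + 1L else integer(0)
    ie_ <- if (length(s) > 1) s[-1] - 1L else integer(0)
    keep <- ie_ >= is_
    list(chrom = as.character(seqnames(models$exons))[k[1]],
         strand = as.character(strand(models$exons))[k[1]],
         ex_s = s, ex_e = e, in_s = is_[keep], in_e = ie_[keep])
  })
  ws <- start(windows); we <- end(windows)
  wchr <- as.character(seqnames(windows))
  wstr <- as.character(strand(windows))
  wgid <- mcols(windows)$gene_id
  ov1 <- function(s1, e1, s2, e2) min(e1, e2) - max(s1, s2) + 1 >= 1
  out <- matrix(0L, 3L * length(gid), 1L,
                dimnames = list(c(paste0(gid, ":exon"), paste0(gid, ":intron"),
                                  paste0(gid, ":ij")), NULL))
  for (r in seq_along(rs)) {
    for (i in seq_along(gid)) {
      g <- genes[[i]]
      if (rc[r] != g$chrom) next
      if (stranded && rstr[r] != g$strand) next
      exhit <- any(re[r] >= g$ex_s & rs[r] <= g$ex_e)
      inhit <- length(g$in_s) > 0 && any(re[r] >= g$in_s & rs[r] <= g$in_e)
      if (exhit) out[i, 1] <- out[i, 1] + 1L
      else if (inhit) out[length(gid) + i, 1] <- out[length(gid) + i, 1] + 1L
    }
    for (i in seq_along(ws)) {
      if (rc[r] != wchr[i]) next
      if (stranded && rstr[r] != wstr[i]) next
      if (ov1(rs[r], re[r], ws[i], we[i]))
        out[paste0(wgid[i], ":ij"), 1] <- out[paste0(wgid[i], ":ij"), 1] + 1L
    }
  }
  out
}

# naive substring scan oracle (loop + substr), 0-based offsets
oracle_scan <- function(motif, target) {
  motif <- chartr("Tt", "Uu", toupper(motif))
  target <- chartr("Tt", "Uu", toupper(target))
  m <- nchar(motif); n <- nchar(target)
  hits <- integer(0)
  for (i in seq_len(max(0L, n - m + 1L)))
    if (substr(target, i, i + m - 1L) == motif) hits <- c(hits, i - 1L)
  hits
}

# exhaustive 4^W enumeration oracle for PWM tail probabilities
oracle_pvalue <- function(pw, score, pseudocount = 1e-4, slack = 0) {
  p <- sweep(pw$probs + pseudocount, 2, colSums(pw$probs + pseudocount), "/")
  lo <- log(p / pw$background)
  W <- pw$width
  words <- as.matrix(expand.grid(rep(list(1:4), W)))
  sc <- numeric(nrow(words)); pr <- numeric(nrow(words))
  for (r in seq_len(nrow(words))) {
    sc[r] <- sum(lo[cbind(words[r, ], 1:W)])
    pr[r] <- prod(pw$background[words[r, ]])
  }
  sum(pr[sc >= score - slack])
}

# interval union oracle over integer basepairs
oracle_union_bp <- function(span_s, span_e, rep_s, rep_e) {
  covered <- logical(span_e - span_s + 1L)
  for (j in seq_along(rep_s)) {
    lo <- max(span_s, rep_s[j]); hi <- min(span_e, rep_e[j])
    if (hi >= lo) covered[(lo:hi) - span_s + 1L] <- TRUE
  }
  sum(covered)
}

# small fast sim config for Monte-Carlo style tests
small_sim <- function(seed, ...) {
  sim_config(seed = seed, chrom_length = 120000L,
             n_clean_induced = 2L, n_dog_pairs = 2L, n_intron_ncrna = 1L,
             n_repeat_genes = 1L, n_flat = 10L, n_down = 1L, ...)
}

# run sim -> count -> de -> filter in memory; returns pieces
run_filter_chain <- function(cfg) {
  b <- generate_genome(cfg)
  reads <- simulate_alignments(b)
  w <- ij_window(b$models, b$chrom_lengths)
  ct <- count_features(reads, b$models, w, b$repeats,
                       conditions = attr(reads, "conditions"))
  sf <- size_factors(ct)
  fc <- fold_changes(ct, sf)
  fcg <- fc[fc$type == "exon", ]
  up <- sub(":exon$", "", classify_de(fcg, 2, 50, "up"))
  metrics <- filter_metrics(up, ct, sf, b$models, b$repeats, w)
  filt <- apply_filters(up, metrics)
  list(bundle = b, ct = ct, sf = sf, fc = fc, up = up, filt = filt,
       windows = w)
}
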