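# -- Synthetic genome / alignment generator with planted ground truth -------

#' Simulation configuration
#'
#' Defaults describe a desk-scale caricature of a heat-shock RNA-seq
#' experiment in a compact genome: three biological replicates per condition,
#' negative-binomial counts with dispersion 0.1, log-normal depth factors,
#' strongly induced "source" genes shedding exponentially decaying
#' readthrough tails into same-strand downstream "victim" genes, genes with
#' HS-only intron-resident ncRNA signal, and induced genes overlapped > 50%
#' by a repetitive element. Gene classes and their baseline means / fold
#' changes are fixed here, not tuned per run.
#'
#' @param seed integer RNG seed; recorded in the output manifest.
#' @param n_chromosomes,chrom_length genome shape (bp).
#' @param read_length simulated read length (single-end intervals).
#' @param n_replicates replicates per condition.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param depth_sdlog sdlog of log-normal per-sample depth factors.
#' @param n_clean_induced,n_dog_pairs,n_intron_ncrna,n_repeat_genes,n_flat,n_down
#'   gene counts per class (a DoG pair is one source plus one victim).
#' @param induced_log2fc_range range of log2 fold change for induced genes.
#' @param source_fc fold change of readthrough source genes.
#' @param readthrough_fraction readthrough read count as a fraction of the
#'   source gene's HS expression.
#' @param decay_length exponential decay length (bp) of the readthrough tail.
#' @param intron_signal_mean HS-only read count of an intron-resident ncRNA.
#' @param intron_exon_bleed fraction of intronic-ncRNA reads crossing into
#'   the flanking exon (3'-extended forms).
#' @param repeat_overlap target repeat-overlap fraction for repeat genes.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 1L, chrom_length = 500000L,
                       read_length = 100L, n_replicates = 3L,
                       dispersion = 0.1, depth_sdlog = 0.2,
                       n_clean_induced = 6L, n_dog_pairs = 4L,
                       n_intron_ncrna = 3L, n_repeat_genes = 3L,
                       n_flat = 40L, n_down = 4L,
                       induced_log2fc_range = c(2, 5), source_fc = 60,
                       readthrough_fraction = 0.6, decay_length = 2500,
                       intron_signal_mean = 600, intron_exon_bleed = 0.2,
                       repeat_overlap = 0.6) {
  cfg <- as.list(environment())
  with(cfg, stopifnot(
    n_chromosomes >= 1, chrom_length > 0, read_length > 0, n_replicates >= 1,
    dispersion > 0, decay_length > 0, readthrough_fraction >= 0,
    repeat_overlap > 0, repeat_overlap < 1,
    n_clean_induced >= 0, n_dog_pairs >= 0, n_intron_ncrna >= 0,
    n_repeat_genes >= 0, n_flat >= 0, n_down >= 0))
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# one gene structure: exon/intron widths; returns list(exon_w, intron_w)
gene_structure <- function() {
  n_ex <- sample(3:5, 1L)
  list(exon_w = sample(150:350, n_ex, replace = TRUE),
       intron_w = sample(400:900, n_ex - 1L, replace = TRUE))
}

#' Generate a synthetic genome bundle with planted ground truth
#'
#' Lays out gene "units" (clean induced, DoG source+victim pairs,
#' intronic-ncRNA genes, repeat-overlapped genes, flat and downregulated
#' genes) along random-sequence chromosomes with intergenic gaps; a DoG
#' victim sits 400-800 bp downstream (in the transcription direction) of its
#' source on the same strand, followed by a 4-kb spacer that insulates
#' the next unit from the readthrough tail. Repeat intervals are placed to
#' achieve the configured overlap fraction for repeat genes, plus scattered
#' low-overlap background repeats. Fully deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_bundle`: `genome` (DNAStringSet), `models`
#'   (gene_model_set), `repeats` (GRanges with mcol `name`), `truth`
#'   (data.frame), `chrom_lengths`, `config`.
#' @export
generate_genome <- function(config = sim_config()) {
  stopifnot(is(config, "sim_config"))
  set.seed(config$seed)
  classes <- c(rep("dog_pair", config$n_dog_pairs),
               rep("clean_induced", config$n_clean_induced),
               rep("intron_ncrna", config$n_intron_ncrna),
               rep("repeat_gene", config$n_repeat_genes),
               rep("flat", config$n_flat),
               rep("down", config$n_down))
  classes <- if (length(classes)) sample(classes) else character(0)

  chroms <- paste0("chr", as.roman(seq_len(config$n_chromosomes)))
  chrom_lengths <- setNames(rep(config$chrom_length, length(chroms)), chroms)

  exon_list <- list(); gene_rows <- list(); truth_rows <- list()
  rep_rows <- list(); utr_rows <- list()
  chrom_i <- 1L
  cursor <- sample(1000:2000, 1L)
  gi <- 0L

  # plain-vector gene layout; GRanges are assembled once at the end
  place_gene <- function(class, chrom, at, strand) {
    st <- gene_structure()
    widths <- c(rbind(st$exon_w, c(st$intron_w, NA)))
    widths <- widths[!is.na(widths)]
    starts <- at + cumsum(c(0L, widths[-length(widths)]))
    is_exon <- rep(c(TRUE, FALSE), length.out = length(widths))
    ex_s <- starts[is_exon]; ex_e <- ex_s + widths[is_exon] - 1L
    gi <<- gi + 1L
    id <- sprintf("g%03d", gi)
    # 3'UTR: terminal 150 bp of the last exon in transcription direction
    li <- if (strand == "+") length(ex_s) else 1L
    utr_w <- min(150L, ex_e[li] - ex_s[li] + 1L)
    utr <- if (strand == "+") c(ex_e[li] - utr_w + 1L, ex_e[li]) else
      c(ex_s[li], ex_s[li] + utr_w - 1L)
    list(id = id, chrom = chrom, strand = strand,
         exons = data.frame(chrom = chrom, start = ex_s, end = ex_e,
                            strand = strand, gene_id = id,
                            transcript_id = paste0(id, ".t1")),
         span_s = ex_s[1], span_e = ex_e[length(ex_e)],
         utr = data.frame(chrom = chrom, start = utr[1], end = utr[2],
                          strand = strand, gene_id = id,
                          transcript_id = paste0(id, ".t1")))
  }

  for (cls in classes) {
    pair <- cls == "dog_pair"
    need <- if (pair) 12000L else 6000L
    while (cursor + need > chrom_lengths[chrom_i] - 1000L) {
      chrom_i <- chrom_i + 1L
      if (chrom_i > length(chroms))
        stop("genes cannot be placed in the configured genome size; ",
             "increase chrom_length or n_chromosomes")
      cursor <- sample(1000:2000, 1L)
    }
    chrom <- chroms[chrom_i]
    strand <- sample(c("+", "-"), 1L)
    if (pair) {
      gap <- sample(400:800, 1L)
      a <- place_gene("src", chrom, cursor, strand)
      b <- place_gene("vic", chrom, a$span_e + gap + 1L, strand)
      # source must be upstream in transcription direction:
      # on '-' the source sits at higher coordinates
      if (strand == "+") { src <- a; vic <- b } else { src <- b; vic <- a }
      for (g in list(src, vic)) {
        exon_list[[g$id]] <- g$exons; utr_rows[[g$id]] <- g$utr
      }
      fc_src <- config$source_fc * 2^runif(1, -0.5, 0.5)
      gene_rows[[src$id]] <- data.frame(
        gene_id = src$id, chrom = chrom, start = src$span_s,
        end = src$span_e, strand = strand, biotype = "protein_coding")
      gene_rows[[vic$id]] <- data.frame(
        gene_id = vic$id, chrom = chrom, start = vic$span_s,
        end = vic$span_e, strand = strand, biotype = "protein_coding")
      truth_rows[[src$id]] <- data.frame(
        gene_id = src$id, class = "dog_source", is_truly_induced = TRUE,
        has_readthrough_contamination = FALSE, has_intronic_ncrna = FALSE,
        baseline_mean = 20, fc = fc_src, readthrough_source = NA_character_)
      truth_rows[[vic$id]] <- data.frame(
        gene_id = vic$id, class = "dog_victim", is_truly_induced = FALSE,
        has_readthrough_contamination = TRUE, has_intronic_ncrna = FALSE,
        baseline_mean = 15, fc = 1, readthrough_source = src$id)
      cursor <- max(a$span_e, b$span_e) + 4000L + sample(1500:2500, 1L)
    } else {
      g <- place_gene(cls, chrom, cursor, strand)
      exon_list[[g$id]] <- g$exons; utr_rows[[g$id]] <- g$utr
      info <- switch(cls,
        clean_induced = list(bt = "protein_coding", ind = TRUE, bl = 30,
                             fc = 2^runif(1, config$induced_log2fc_range[1],
                                          config$induced_log2fc_range[2])),
        intron_ncrna = list(bt = "protein_coding", ind = FALSE, bl = 25, fc = 1),
        repeat_gene = list(bt = "protein_coding", ind = TRUE, bl = 30,
                           fc = 2^runif(1, config$induced_log2fc_range[1],
                                        config$induced_log2fc_range[2])),
        flat = list(bt = "protein_coding", ind = FALSE, bl = 50, fc = 1),
        down = list(bt = "protein_coding", ind = FALSE, bl = 200,
                    fc = 2^-runif(1, 1.5, 3)))
      gene_rows[[g$id]] <- data.frame(
        gene_id = g$id, chrom = chrom, start = g$span_s,
        end = g$span_e, strand = strand, biotype = info$bt)
      truth_rows[[g$id]] <- data.frame(
        gene_id = g$id, class = cls, is_truly_induced = info$ind,
        has_readthrough_contamination = FALSE,
        has_intronic_ncrna = cls == "intron_ncrna",
        baseline_mean = info$bl, fc = info$fc,
        readthrough_source = NA_character_)
      if (cls == "repeat_gene") {
        sp_w <- g$span_e - g$span_s + 1L
        f <- config$repeat_overlap + runif(1, -0.03, 0.03)
        rw <- round(f * sp_w)
        rs <- g$span_s + sample.int(sp_w - rw + 1L, 1L) - 1L
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          chrom = chrom, start = rs, end = rs + rw - 1L,
          name = sprintf("repfam%02d", length(rep_rows) + 1L))
      }
      cursor <- g$span_e + sample(1500:2500, 1L)
    }
  }

  gdf <- do.call(rbind, unname(gene_rows))
  truth <- do.call(rbind, unname(truth_rows))
  if (is.null(gdf)) {
    genes <- GRanges(); mcols(genes)$gene_id <- character(0)
    mcols(genes)$biotype <- character(0)
    exons <- GRanges(); mcols(exons)$gene_id <- character(0)
    mcols(exons)$transcript_id <- character(0)
    models <- gene_model_set(genes, exons)
    truth <- data.frame(gene_id = character(0))
  } else {
    genes <- GRanges(gdf$chrom, IRanges(gdf$start, gdf$end),
                     strand = gdf$strand)
    mcols(genes)$gene_id <- gdf$gene_id
    mcols(genes)$biotype <- gdf$biotype
    edf <- do.call(rbind, unname(exon_list))
    exons <- GRanges(edf$chrom, IRanges(edf$start, edf$end),
                     strand = edf$strand)
    mcols(exons)$gene_id <- edf$gene_id
    mcols(exons)$transcript_id <- edf$transcript_id
    udf <- do.call(rbind, unname(utr_rows))
    utr3 <- GRanges(udf$chrom, IRanges(udf$start, udf$end),
                    strand = udf$strand)
    mcols(utr3)$gene_id <- udf$gene_id
    mcols(utr3)$transcript_id <- udf$transcript_id
    models <- gene_model_set(genes, exons, utr3)
  }

  # background repeats: low-overlap scatter in intergenic space
  n_bg <- 8L
  for (b in seq_len(n_bg)) {
    w <- sample(200:600, 1L)
    for (try in 1:50) {
      ch <- sample(chroms, 1L)
      s <- sample.int(chrom_lengths[ch] - w, 1L)
      clash <- !is.null(gdf) &&
        any(gdf$chrom == ch & s <= gdf$end & s + w - 1L >= gdf$start)
      if (!clash) {
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          chrom = ch, start = s, end = s + w - 1L,
          name = sprintf("bgrep%02d", b))
        break
      }
    }
  }
  repeats <- if (length(rep_rows)) {
    rdf <- do.call(rbind, rep_rows)
    r <- GRanges(rdf$chrom, IRanges(rdf$start, rdf$end))
    mcols(r)$name <- rdf$name
    r
  } else {
    r <- GRanges(); mcols(r)$name <- character(0); r
  }

  if (nrow(truth) > 0L) {
    spans <- models$genes[match(truth$gene_id, mcols(models$genes)$gene_id)]
    red <- reduce(repeats, ignore.strand = TRUE)
    cov <- numeric(length(spans))
    h <- findOverlaps(spans, red, ignore.strand = TRUE)
    if (length(h) > 0L) {
      wv <- width(pintersect(spans[queryHits(h)], red[subjectHits(h)],
                             ignore.strand = TRUE))
      agg <- tapply(wv, queryHits(h), sum)
      cov[as.integer(names(agg))] <- agg
    }
    truth$repeat_overlap_fraction <- cov / width(spans)
  }

  genome <- DNAStringSet(setNames(
    vapply(chroms, function(ch) random_dna(chrom_lengths[ch]), ""), chroms))

  structure(list(genome = genome, models = models, repeats = repeats,
                 truth = truth, chrom_lengths = chrom_lengths,
                 config = config),
            class = "sim_bundle")
}

# start positions of n reads of length rl with 5' ends uniform in exons
# (weighted by width), extending downstream in transcription direction;
# returns read start coordinates (plus-strand convention)
exonic_read_starts <- function(ex_s, ex_e, n, rl, strand) {
  if (n == 0L) return(integer(0))
  w <- ex_e - ex_s + 1L
  pick <- sample.int(length(ex_s), n, replace = TRUE, prob = w)
  pos <- ex_s[pick] + floor(runif(n) * w[pick])
  if (strand == "+") pos else pmax(1L, pos - rl + 1L)
}

#' Simulate per-sample read alignments from a genome bundle
#'
#' For every gene and sample, the exonic read count is drawn from a
#' negative binomial with mean `baseline * fc(condition) * depth`; reads are
#' placed with 5' ends uniform within exons. Readthrough sources
#' additionally shed, in HS samples only, reads whose distance past the
#' gene's 3' end is exponential with the configured decay length, crossing
#' the downstream victim's IJ window, introns and exons. Intronic-ncRNA
#' genes receive HS-only reads confined to their widest intron, with a small
#' fraction crossing into the flanking exon (3'-extended forms). All reads
#' carry the strand of their source gene.
#'
#' @param bundle a `sim_bundle` from [generate_genome()].
#' @param config defaults to `bundle$config`.
#' @return Named list of `GRanges`, one per sample (CTRL_1..n, HS_1..n),
#'   with a `depth` attribute giving the per-sample depth factors.
#' @export
simulate_alignments <- function(bundle, config = bundle$config) {
  stopifnot(is(bundle, "sim_bundle"))
  set.seed(config$seed + 1L)
  nrep <- config$n_replicates
  samples <- c(paste0("CTRL_", seq_len(nrep)), paste0("HS_", seq_len(nrep)))
  cond <- rep(c("CTRL", "HS"), each = nrep)
  depth <- setNames(rlnorm(length(samples), 0, config$depth_sdlog), samples)
  rl <- config$read_length
  truth <- bundle$truth
  models <- bundle$models
  size <- 1 / config$dispersion
  # pre-extract plain-vector gene structures once
  gid_all <- mcols(models$genes)$gene_id
  ex_by_gene <- split(data.frame(s = start(models$exons), e = end(models$exons)),
                      mcols(models$exons)$gene_id)
  gene_chrom <- as.character(seqnames(models$genes))
  gene_strand <- as.character(strand(models$genes))
  gene_s <- start(models$genes); gene_e <- end(models$genes)
  widest_intron <- function(id) {
    ex <- ex_by_gene[[id]]
    o <- order(ex$s)
    if (nrow(ex) < 2L) return(NULL)
    is_ <- ex$e[o][-nrow(ex)] + 1L; ie_ <- ex$s[o][-1] - 1L
    j <- which.max(ie_ - is_)
    c(is_[j], ie_[j])
  }
  out <- list()
  for (k in seq_along(samples)) {
    s <- samples[k]; is_hs <- cond[k] == "HS"
    r_chrom <- character(0); r_start <- integer(0); r_strand <- character(0)
    add <- function(chrom, st, strand, n) {
      r_chrom <<- c(r_chrom, rep(chrom, n))
      r_start <<- c(r_start, as.integer(st))
      r_strand <<- c(r_strand, rep(strand, n))
    }
    for (i in seq_len(nrow(truth))) {
      id <- truth$gene_id[i]
      gi <- match(id, gid_all)
      ex <- ex_by_gene[[id]]
      strand <- gene_strand[gi]; chrom <- gene_chrom[gi]
      mu <- truth$baseline_mean[i] * (if (is_hs) truth$fc[i] else 1) * depth[k]
      n <- rnbinom(1L, mu = mu, size = size)
      if (n > 0L)
        add(chrom, exonic_read_starts(ex$s, ex$e, n, rl, strand), strand, n)
      if (is_hs && truth$class[i] == "dog_source" &&
          config$readthrough_fraction > 0) {
        mu_rt <- truth$baseline_mean[i] * truth$fc[i] *
          config$readthrough_fraction * depth[k]
        n_rt <- rnbinom(1L, mu = mu_rt, size = size)
        if (n_rt > 0L) {
          d <- pmax(1, round(rexp(n_rt, 1 / config$decay_length)))
          st <- if (strand == "+") gene_e[gi] + d else
            pmax(1L, gene_s[gi] - d - rl + 1L)
          add(chrom, st, strand, n_rt)
        }
      }
      if (is_hs && truth$class[i] == "intron_ncrna") {
        intr <- widest_intron(id)
        n_nc <- rnbinom(1L, mu = config$intron_signal_mean * depth[k],
                        size = size)
        iw <- if (is.null(intr)) 0L else intr[2] - intr[1] + 1L
        if (n_nc > 0L && iw > rl + 2L) {
          bleed <- runif(n_nc) < config$intron_exon_bleed
          st <- integer(n_nc)
          st[!bleed] <- intr[1] + floor(runif(sum(!bleed)) * (iw - rl))
          st[bleed] <- intr[2] - rl + 1L +
            floor(runif(sum(bleed)) * (rl - 1L)) + 1L
          add(chrom, st, strand, n_nc)
        }
      }
    }
    gr <- GRanges(r_chrom, IRanges(r_start, width = rl), strand = r_strand)
    # drop readthrough tails that run past the chromosome, clamp the rest
    len <- unname(bundle$chrom_lengths[r_chrom])
    gr <- gr[start(gr) <= len & end(gr) >= 1L]
    gr <- clip_to_chrom(gr, bundle$chrom_lengths)
    mcols(gr)$edge_clipped <- NULL
    mcols(gr)$name <- sprintf("%s_r%06d", s, seq_along(gr))
    mcols(gr)$score <- 0L
    out[[s]] <- sort(gr, ignore.strand = TRUE)
  }
  attr(out, "depth") <- depth
  attr(out, "conditions") <- setNames(cond, samples)
  out
}

#' Write a simulation bundle and reads to standard-format files
#'
#' Emits genome FASTA, gene GTF, repeat BED, chrom sizes TSV, per-sample
#' read BED6, truth TSV and a JSON manifest carrying the config and seed.
#'
#' @param bundle a `sim_bundle`.
#' @param reads list from [simulate_alignments()] (optional).
#' @param dir output directory (created if needed).
#' @return Invisibly, the named list of file paths.
#' @export
write_bundle <- function(bundle, reads = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list(genome = file.path(dir, "genome.fa"),
            gtf = file.path(dir, "genes.gtf"),
            repeats = file.path(dir, "repeats.bed"),
            sizes = file.path(dir, "chrom.sizes"),
            truth = file.path(dir, "truth_genes.tsv"),
            manifest = file.path(dir, "sim_manifest.json"))
  writeXStringSet(bundle$genome, p$genome)
  write_gene_models(bundle$models, p$gtf)
  rtracklayer::export(bundle$repeats, p$repeats, format = "bed")
  write_chrom_sizes(bundle$chrom_lengths, p$sizes)
  write_tsv(bundle$truth, p$truth)
  if (!is.null(reads)) {
    for (s in names(reads)) {
      f <- file.path(dir, sprintf("reads_%s.bed", s))
      rtracklayer::export(reads[[s]], f, format = "bed")
      p[[paste0("reads_", s)]] <- f
    }
  }
  jsonlite::write_json(
    list(config = unclass(bundle$config),
         seed = bundle$config$seed,
         n_genes = length(bundle$models$genes)),
    p$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(p)
}
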