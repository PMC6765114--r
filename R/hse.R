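# -- PWM motif scanning with exact p-values; HSE / summit classification ----

DNA_BASES <- c("A", "C", "G", "T")

#' Read a motif in MEME minimal text format
#'
#' Parses the first motif of a MEME minimal-format file: the optional
#' `Background letter frequencies` block and the `letter-probability matrix`.
#'
#' @param path path to a MEME minimal motif file.
#' @return list of class `pwm`: `name`, `probs` (4 x W matrix, rows ACGT),
#'   `background` (named length-4 vector), `width`.
#' @export
read_meme <- function(path) {
  lines <- trimws(readLines(path))
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl) > 0L) {
    tok <- strsplit(lines[bgl[1] + 1L], "\\s+")[[1]]
    v <- as.numeric(tok[c(FALSE, TRUE)])
    names(v) <- tok[c(TRUE, FALSE)]
    bg[names(v)] <- v
  }
  mot <- grep("^MOTIF\\b", lines)
  if (length(mot) == 0L) stop("no MOTIF block in ", path)
  name <- sub("^MOTIF\\s+", "", lines[mot[1]])
  hdr <- grep("^letter-probability matrix", lines)
  hdr <- hdr[hdr > mot[1]][1]
  if (is.na(hdr)) stop("no letter-probability matrix in ", path)
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
  rows <- lines[(hdr + 1L):(hdr + w)]
  probs <- t(vapply(strsplit(rows, "\\s+"),
                    function(x) as.numeric(x[nzchar(x)]), numeric(4)))
  pwm(t(probs), background = bg, name = name)
}

#' Construct a PWM object
#'
#' @param probs 4 x W matrix of per-position base probabilities (rows in
#'   A, C, G, T order; columns must each sum to ~1).
#' @param background named background distribution over ACGT (default
#'   uniform).
#' @param name motif name.
#' @return list of class `pwm`.
#' @export
pwm <- function(probs, background = c(A = .25, C = .25, G = .25, T = .25),
                name = "motif") {
  stopifnot(is.matrix(probs), nrow(probs) == 4L)
  rownames(probs) <- DNA_BASES
  if (any(abs(colSums(probs) - 1) > 1e-3))
    stop("PWM columns must sum to 1")
  if (any(background <= 0)) stop("background must be strictly positive")
  background <- background[DNA_BASES] / sum(background[DNA_BASES])
  structure(list(name = name, probs = probs, background = background,
                 width = ncol(probs)), class = "pwm")
}

#' Write a PWM in MEME minimal format
#' @param x a `pwm`.
#' @param path output path.
#' @export
write_meme <- function(x, path) {
  stopifnot(is(x, "pwm"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, x$background),
                     collapse = " "), "",
               paste("MOTIF", x$name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       x$width),
               apply(x$probs, 2L, function(p)
                 paste(sprintf("%.6f", p), collapse = "  "))), con)
  invisible(path)
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm '", x$name, "': width ", x$width, ", consensus ",
      pwm_consensus(x), "\n", sep = "")
  invisible(x)
}

#' Consensus (highest-probability base per column) of a PWM
#' @param x a `pwm`.
#' @return Character string of length `width`.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$probs, 2L, which.max)], collapse = "")
}

# Log-odds matrix (natural log) after pseudocounting and renormalizing the
# probabilities. 4 x W, rows ACGT.
pwm_logodds <- function(x, pseudocount = 1e-4) {
  p <- sweep(x$probs + pseudocount, 2L, colSums(x$probs + pseudocount), "/")
  log(p / x$background)
}

#' Log-odds score of one sequence window against a PWM
#'
#' Sum over positions of `log(p_pos(base) / background(base))`; for the `-`
#' strand the reverse complement of the window is scored. Windows containing
#' ambiguous bases (N) score `NA` and are skipped by the scanner.
#'
#' @param x a `pwm`.
#' @param window character string of length `width`.
#' @param strand `"+"` or `"-"`.
#' @param pseudocount PWM pseudocount (default 1e-4).
#' @return Numeric score (natural log).
#' @export
score_window <- function(x, window, strand = "+", pseudocount = 1e-4) {
  stopifnot(nchar(window) == x$width)
  if (strand == "-")
    window <- as.character(reverseComplement(DNAStringSet(window)))
  lo <- pwm_logodds(x, pseudocount)
  code <- match(strsplit(toupper(window), "")[[1]], DNA_BASES)
  if (anyNA(code)) return(NA_real_)
  sum(lo[cbind(code, seq_len(x$width))])
}

# Discretized scoring scheme shared by the scanner and the null
# distribution, guaranteeing that window scores and the DP distribution live
# on the same integer grid. K[c, j] = integer score of base c at column j.
pwm_scheme <- function(x, pseudocount = 1e-4, bins = 1000L) {
  lo <- pwm_logodds(x, pseudocount)
  rng <- sum(apply(lo, 2L, max)) - sum(apply(lo, 2L, min))
  g <- if (rng > 0) rng / bins else 1
  colmin <- apply(lo, 2L, min)
  K <- round(sweep(lo, 2L, colmin, "-") / g)
  list(lo = lo, K = K, g = g, offset = sum(colmin))
}

# Exact distribution of the integer score of a background-generated W-mer:
# column-by-column convolution. Returns the tail probability vector `tail`
# with tail[k + 1] = P(K_total >= k).
pwm_null <- function(x, pseudocount = 1e-4, bins = 1000L) {
  sc <- pwm_scheme(x, pseudocount, bins)
  bg <- x$background
  dist <- 1
  for (j in seq_len(x$width)) {
    kmax <- max(sc$K[, j])
    col <- numeric(kmax + 1L)
    for (c_ in 1:4) col[sc$K[c_, j] + 1L] <- col[sc$K[c_, j] + 1L] + bg[c_]
    dist <- convolve_counts(dist, col)
  }
  tail <- rev(cumsum(rev(dist)))
  tail <- pmin(tail, 1)
  c(sc, list(tail = tail))
}

# plain O(n*m) convolution of two probability vectors indexed from 0
convolve_counts <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(b)) {
    if (b[i] > 0)
      out[i:(i + length(a) - 1L)] <- out[i:(i + length(a) - 1L)] + a * b[i]
  }
  out
}

#' Exact p-value of a PWM log-odds score
#'
#' Probability that a background-generated W-mer scores at or above `score`,
#' computed by exact dynamic programming over the discretized per-column
#' score distribution (default granularity: 1/1000 of the attainable score
#' range). Scores below the minimum attainable give p = 1.
#'
#' @param x a `pwm`.
#' @param score log-odds score (natural log).
#' @param pseudocount PWM pseudocount.
#' @param bins discretization bins over the score range.
#' @return p-value in (0, 1].
#' @export
score_pvalue <- function(x, score, pseudocount = 1e-4, bins = 1000L) {
  if (!is.finite(score)) stop("score must be finite")
  null <- pwm_null(x, pseudocount, bins)
  k <- round((score - null$offset) / null$g)
  if (k <= 0L) return(1)
  if (k + 1L > length(null$tail)) return(null$tail[length(null$tail)])
  null$tail[k + 1L]
}

#' Scan sequences on both strands for PWM hits below a p-value threshold
#'
#' FIMO-style scan: every window on both strands whose exact background
#' p-value is below `p_threshold` is reported; overlapping hits are all
#' kept. Windows containing N are skipped.
#'
#' @param x a `pwm`.
#' @param seqs named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param p_threshold report hits with p < this value (default 1e-4).
#' @param pseudocount,bins see [score_pvalue()].
#' @return `GRanges` of hits with mcols `score` and `p_value`.
#' @export
scan_genome <- function(x, seqs, p_threshold = 1e-4, pseudocount = 1e-4,
                        bins = 1000L) {
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  stopifnot(!is.null(names(seqs)))
  null <- pwm_null(x, pseudocount, bins)
  W <- x$width
  hit_list <- list()
  for (chrom in names(seqs)) {
    L <- nchar(seqs[[chrom]])
    if (L < W) next
    for (str in c("+", "-")) {
      s <- if (str == "+") seqs[[chrom]] else
        as.character(reverseComplement(DNAStringSet(seqs[[chrom]])))
      code <- match(strsplit(toupper(s), "")[[1]], DNA_BASES)
      n <- L - W + 1L
      ks <- numeric(n); valid <- rep(TRUE, n)
      for (j in seq_len(W)) {
        cj <- code[j:(n + j - 1L)]
        bad <- is.na(cj)
        valid <- valid & !bad
        cj[bad] <- 1L
        ks <- ks + null$K[cbind(cj, j)]
      }
      p <- null$tail[pmin(ks, length(null$tail) - 1L) + 1L]
      keep <- which(valid & p < p_threshold)
      if (length(keep) == 0L) next
      starts <- if (str == "+") keep else L - (keep + W - 1L) + 1L
      hit_list[[length(hit_list) + 1L]] <-
        GRanges(chrom, IRanges(starts, width = W), strand = str,
                score = null$offset + ks[keep] * null$g,
                p_value = p[keep])
    }
  }
  if (length(hit_list) == 0L) {
    out <- GRanges()
    mcols(out)$score <- numeric(0); mcols(out)$p_value <- numeric(0)
    return(out)
  }
  sort(do.call(c, hit_list), ignore.strand = TRUE)
}

#' 201-bp regions centered on ChIP summits
#'
#' Each summit position s (1-based) yields the window `[s - 100, s + 100]`
#' (width 201); windows running off a chromosome edge are clipped and
#' flagged. Summits are treated independently (no merging).
#'
#' @param summits `GRanges` of single-base summit positions (e.g. imported
#'   from a summit BED), or a BED path.
#' @param chrom_lengths optional named vector for edge clipping.
#' @param half_width bases on each side of the summit (default 100).
#' @return `GRanges` with mcols `summit` (1-based position) and
#'   `edge_clipped`.
#' @export
summit_regions <- function(summits, chrom_lengths = NULL, half_width = 100L) {
  if (is.character(summits)) summits <- rtracklayer::import(summits)
  pos <- start(summits)
  reg <- GRanges(seqnames(summits), IRanges(pos - half_width, pos + half_width))
  mcols(reg)$summit <- pos
  clip_to_chrom(reg, chrom_lengths)
}

#' Classify motif hits as bound or unbound by summit-region overlap
#'
#' A hit is "bound" when its maximum overlap over all summit regions is at
#' least `min_overlap` bp (default 14). Hit strand is ignored: a motif
#' instance on either strand can be bound.
#'
#' @param hits `GRanges` of motif hits from [scan_genome()].
#' @param regions `GRanges` from [summit_regions()].
#' @param min_overlap minimum overlap in bp (default 14).
#' @return data.frame: chrom, start, end, strand, score, p_value,
#'   max_overlap_bp, bound.
#' @export
classify_bound <- function(hits, regions, min_overlap = 14L) {
  mo <- integer(length(hits))
  if (length(hits) > 0L && length(regions) > 0L) {
    h <- findOverlaps(hits, regions, ignore.strand = TRUE)
    if (length(h) > 0L) {
      w <- width(pintersect(hits[queryHits(h)], regions[subjectHits(h)],
                            ignore.strand = TRUE))
      agg <- tapply(w, queryHits(h), max)
      mo[as.integer(names(agg))] <- as.integer(agg)
    }
  }
  data.frame(chrom = as.character(seqnames(hits)),
             start = start(hits), end = end(hits),
             strand = as.character(strand(hits)),
             score = if (length(hits)) mcols(hits)$score else numeric(0),
             p_value = if (length(hits)) mcols(hits)$p_value else numeric(0),
             max_overlap_bp = mo,
             bound = mo >= min_overlap,
             stringsAsFactors = FALSE)
}

#' Per-gene promoter HSE report
#'
#' For each gene, counts motif hits overlapping its promoter (strand-aware
#' 1-kb window upstream of the annotated start, excluding the start base)
#' and how many of those are classified bound; `has_bound_hse` flags genes
#' with at least one bound promoter HSE.
#'
#' @param models a `gene_model_set`.
#' @param hits `GRanges` of motif hits.
#' @param calls data.frame from [classify_bound()] aligned with `hits`, or
#'   NULL (all hits treated as unbound).
#' @param promoter_bp promoter size (default 1000).
#' @param chrom_lengths optional, for edge clipping.
#' @return data.frame: gene_id, n_hse, n_bound, has_bound_hse.
#' @export
promoter_hse_report <- function(models, hits, calls = NULL,
                                promoter_bp = 1000L, chrom_lengths = NULL) {
  prom <- promoter_windows(models, promoter_bp, chrom_lengths)
  n_hse <- integer(length(prom)); n_bound <- integer(length(prom))
  if (length(hits) > 0L) {
    h <- findOverlaps(prom, hits, ignore.strand = TRUE)
    if (length(h) > 0L) {
      tab <- table(factor(queryHits(h), levels = seq_along(prom)))
      n_hse <- as.integer(tab)
      if (!is.null(calls)) {
        bh <- h[calls$bound[subjectHits(h)]]
        tb <- table(factor(queryHits(bh), levels = seq_along(prom)))
        n_bound <- as.integer(tb)
      }
    }
  }
  data.frame(gene_id = mcols(prom)$gene_id, n_hse = n_hse,
             n_bound = n_bound, has_bound_hse = n_bound > 0L,
             stringsAsFactors = FALSE)
}
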