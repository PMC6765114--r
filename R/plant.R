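# -- Planting ground-truth seed sites and motif instances -------------------

#' Random UTR-like background sequences
#'
#' @param n number of sequences.
#' @param length length of each (nt).
#' @param ids names (default utr1..utrn).
#' @return Named character vector of RNA sequences.
#' @export
random_utrs <- function(n, length = 400L, ids = paste0("utr", seq_len(n))) {
  setNames(vapply(seq_len(n), function(i)
    chartr("T", "U", random_dna(length)), ""), ids)
}

# remove every occurrence of any motif from seq by re-drawing one base
# inside each occurrence until the sequence is clean; positions in `keep`
# (1-based start:end windows) are left untouched
scrub_motifs <- function(seq, motifs, keep = integer(0)) {
  for (iter in 1:200) {
    occ <- unlist(lapply(motifs, function(m) scan_sites(m, seq) + 1L))
    occ <- occ[!(occ %in% keep)]
    if (length(occ) == 0L) return(seq)
    i <- occ[1] + sample.int(6L, 1L) - 1L
    old <- substr(seq, i, i)
    repl <- sample(setdiff(c("A", "C", "G", "U"), old), 1L)
    substr(seq, i, i) <- repl
  }
  stop("could not scrub background free of seed motifs")
}

#' Plant exact seed sites into UTR sequences
#'
#' Inserts (by overwriting) the reverse-complement 6-mer site of each
#' miRNA's seed at recorded non-overlapping positions. The background is
#' first scrubbed so it contains no spurious site for any miRNA in the set,
#' making planted counts exact ground truth for the scanner.
#'
#' @param utr_sequences named character vector of background sequences (see
#'   [random_utrs()]).
#' @param mirna_set data.frame: `mirna_id`, `sequence`.
#' @param counts data.frame: `mirna_id`, `target_id`, `n_sites` requested.
#' @return list: `sequences` (modified named vector), `truth` (data.frame
#'   mirna_id, target_id, n_sites, positions as comma-separated 0-based
#'   offsets).
#' @export
plant_seed_sites <- function(utr_sequences, mirna_set, counts) {
  stopifnot(all(counts$target_id %in% names(utr_sequences)),
            all(counts$mirna_id %in% mirna_set$mirna_id))
  motifs <- setNames(
    vapply(mirna_set$sequence, function(s) site_motif(seed_of(s)), ""),
    mirna_set$mirna_id)
  out <- utr_sequences
  truth <- list()
  for (tid in unique(names(utr_sequences))) {
    want <- counts[counts$target_id == tid, , drop = FALSE]
    need <- sum(want$n_sites) * 6L
    if (nchar(out[[tid]]) < need + 6L * nrow(want))
      stop("UTR ", tid, " too short for requested planted sites")
    for (attempt in 1:50) {
      seq <- scrub_motifs(out[[tid]], motifs)
      total <- sum(want$n_sites)
      if (total > 0L) {
        # non-overlapping 6-mer slots
        n_slots <- floor(nchar(seq) / 8L)
        if (total > n_slots) stop("UTR ", tid, " too short for planted sites")
        slots <- sort(sample.int(n_slots, total)) * 8L - 7L
        k <- 0L
        for (r in seq_len(nrow(want))) {
          m <- motifs[[want$mirna_id[r]]]
          for (j in seq_len(want$n_sites[r])) {
            k <- k + 1L
            substr(seq, slots[k], slots[k] + 5L) <- m
          }
        }
      }
      # verify exactness for every miRNA in the set
      ok <- TRUE
      for (mid in mirna_set$mirna_id) {
        got <- length(scan_sites(motifs[[mid]], seq))
        exp_n <- sum(want$n_sites[want$mirna_id == mid])
        if (got != exp_n) { ok <- FALSE; break }
      }
      if (ok) {
        out[[tid]] <- seq
        if (sum(want$n_sites) > 0L) {
          k <- 0L
          for (r in seq_len(nrow(want))) {
            pos <- integer(0)
            for (j in seq_len(want$n_sites[r])) {
              k <- k + 1L
              pos <- c(pos, slots[k] - 1L)
            }
            truth[[length(truth) + 1L]] <- data.frame(
              mirna_id = want$mirna_id[r], target_id = tid,
              n_sites = want$n_sites[r],
              positions = paste(pos, collapse = ","),
              stringsAsFactors = FALSE)
          }
        }
        break
      }
      if (attempt == 50L) stop("failed to plant exact sites in ", tid)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(mirna_id = character(0), target_id = character(0),
               n_sites = integer(0), positions = character(0))
  list(sequences = out, truth = truth)
}

#' Plant motif instances near and away from ChIP summits
#'
#' Writes the PWM consensus word into the genome: `n_bound` instances with
#' at least 14 bp overlap of a 201-bp window centered on a (generated)
#' summit, `n_unbound` instances with at most 13 bp overlap or far from any
#' summit. Overlap amounts are sampled per instance; truth records the
#' geometry. Optionally, instances can be directed into specific promoter
#' windows (always bound, centered on a summit placed there).
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param x a `pwm`; its consensus must itself pass the scan threshold.
#' @param n_bound,n_unbound numbers of instances to plant.
#' @param avoid `GRanges` the instances and summits must not touch (e.g.
#'   gene spans), or NULL.
#' @param promoters optional `GRanges`; one bound instance+summit is placed
#'   centrally in each (counted inside `n_bound`).
#' @param p_threshold used only to verify the consensus is detectable.
#' @return list: `genome` (modified), `summits` (GRanges), `truth`
#'   (data.frame: instance_id, chrom, start, end, summit, overlap_bp,
#'   bound).
#' @export
plant_hses <- function(genome, x, n_bound = 5L, n_unbound = 5L,
                       avoid = NULL, promoters = NULL, p_threshold = 1e-4) {
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  W <- x$width
  cons <- pwm_consensus(x)
  if (score_pvalue(x, score_window(x, cons)) >= p_threshold)
    stop("PWM consensus does not pass the detection threshold; ",
         "motif too weak for planting")
  n_prom <- if (is.null(promoters)) 0L else length(promoters)
  if (n_prom > n_bound) stop("more promoter placements than n_bound")
  placed <- GRanges()
  if (!is.null(avoid)) placed <- granges(avoid)
  chroms <- names(genome)
  lens <- setNames(nchar(genome), chroms)
  summits <- list(); truth <- list()
  inst <- 0L

  put <- function(chrom, start) {
    substr(genome[[chrom]], start, start + W - 1L) <<- cons
  }
  reserve <- function(gr) placed <<- suppressWarnings(c(placed, granges(gr)))

  free_spot <- function(width_needed) {
    for (try in 1:500) {
      ch <- sample(chroms, 1L)
      s <- sample.int(lens[ch] - width_needed - 1L, 1L) + 1L
      cand <- GRanges(ch, IRanges(s - 300L, s + width_needed + 300L))
      if (length(placed) == 0L ||
          length(findOverlaps(cand, placed, ignore.strand = TRUE)) == 0L)
        return(list(chrom = ch, start = s))
    }
    stop("no free genomic spot for motif placement; genome too crowded")
  }

  plant_one <- function(summit_pos, chrom, overlap_bp) {
    # region [summit-100, summit+100]; left-edge partial overlap unless full
    reg_s <- summit_pos - 100L
    st <- if (overlap_bp >= W) summit_pos - floor(W / 2) else
      reg_s - (W - overlap_bp)
    inst <<- inst + 1L
    put(chrom, st)
    reserve(GRanges(chrom, IRanges(st, st + W - 1L)))
    truth[[inst]] <<- data.frame(
      instance_id = sprintf("hse%02d", inst), chrom = chrom,
      start = st, end = st + W - 1L, summit = summit_pos,
      overlap_bp = min(overlap_bp, W), bound = min(overlap_bp, W) >= 14L,
      stringsAsFactors = FALSE)
  }

  # promoter-directed bound instances
  if (n_prom > 0L) {
    for (i in seq_len(n_prom)) {
      pr <- promoters[i]
      mid <- start(pr) + floor(width(pr) / 2)
      ch <- as.character(seqnames(pr))
      summits[[length(summits) + 1L]] <- GRanges(ch, IRanges(mid, mid))
      plant_one(mid, ch, W)
      reserve(GRanges(ch, IRanges(mid - 100L, mid + 100L)))
    }
  }
  for (i in seq_len(n_bound - n_prom)) {
    spot <- free_spot(600L)
    sm <- spot$start + 300L
    summits[[length(summits) + 1L]] <-
      GRanges(spot$chrom, IRanges(sm, sm))
    ov <- sample(14:min(W, 201L), 1L)
    plant_one(sm, spot$chrom, ov)
    reserve(GRanges(spot$chrom, IRanges(sm - 100L, sm + 100L)))
  }
  for (i in seq_len(n_unbound)) {
    ov <- sample(0:13, 1L)
    if (ov == 0L) {
      spot <- free_spot(W + 10L)
      put(spot$chrom, spot$start)
      inst <- inst + 1L
      truth[[inst]] <- data.frame(
        instance_id = sprintf("hse%02d", inst), chrom = spot$chrom,
        start = spot$start, end = spot$start + W - 1L,
        summit = NA_integer_, overlap_bp = 0L, bound = FALSE,
        stringsAsFactors = FALSE)
      reserve(GRanges(spot$chrom, IRanges(spot$start, spot$start + W - 1L)))
    } else {
      spot <- free_spot(600L)
      sm <- spot$start + 300L
      summits[[length(summits) + 1L]] <-
        GRanges(spot$chrom, IRanges(sm, sm))
      plant_one(sm, spot$chrom, ov)
      reserve(GRanges(spot$chrom, IRanges(sm - 100L, sm + 100L)))
    }
  }
  sm <- if (length(summits)) suppressWarnings(do.call(c, summits)) else GRanges()
  if (length(sm)) mcols(sm)$name <- sprintf("summit%02d", seq_along(sm))
  list(genome = DNAStringSet(genome), summits = sm,
       truth = do.call(rbind, truth))
}
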