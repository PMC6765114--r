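# -- miRNA seed extraction, seed-site scanning and target networks ----------

rna_norm <- function(x) chartr("Tt", "Uu", toupper(x))

check_rna <- function(x, what = "sequence") {
  if (grepl("[^ACGU]", x))
    stop("invalid ", what, ": letters must be A, C, G, U (or T)")
  x
}

#' Seed sequence of a miRNA (nucleotides 2-7)
#'
#' Target recognition is driven largely by pairing of miRNA nucleotides 2-7,
#' the seed. DNA input (T) is accepted and mapped to RNA.
#'
#' @param mirna_sequence miRNA sequence, 5'->3', length >= 7.
#' @return The 6-nt seed (RNA alphabet).
#' @export
#' @examples
#' seed_of("AUUGCUUUGUGGCUUUGCUGGUAAC")  # "UUGCUU"
seed_of <- function(mirna_sequence) {
  s <- check_rna(rna_norm(mirna_sequence), "miRNA sequence")
  if (nchar(s) < 7L) stop("miRNA sequence shorter than 7 nt; no seed")
  substr(s, 2L, 7L)
}

#' Target-strand seed-site motif
#'
#' The exact site complementary to a seed is its reverse complement, reported
#' 5'->3' in the target (RNA) alphabet.
#'
#' @param seed 6-nt RNA seed from [seed_of()].
#' @return 6-nt site motif.
#' @export
#' @examples
#' site_motif("UUGCUU")  # "AAGCAA"
site_motif <- function(seed) {
  s <- check_rna(rna_norm(seed), "seed")
  paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
}

#' Scan a target sequence for exact seed-site matches
#'
#' Reports the 0-based start offset of every exact occurrence of the site
#' motif in the target; overlapping occurrences are all counted. Input is
#' case-insensitive and T is mapped to U.
#'
#' @param motif site motif from [site_motif()].
#' @param target_sequence target RNA/DNA sequence.
#' @return Integer vector of 0-based offsets (possibly empty).
#' @export
scan_sites <- function(motif, target_sequence) {
  m <- check_rna(rna_norm(motif), "motif")
  t <- check_rna(rna_norm(target_sequence), "target")
  nm <- nchar(m); nt <- nchar(t)
  if (nt < nm) return(integer(0))
  tc <- strsplit(t, "")[[1]]
  mc <- strsplit(m, "")[[1]]
  ok <- rep(TRUE, nt - nm + 1L)
  for (j in seq_len(nm))
    ok <- ok & tc[j:(nt - nm + j)] == mc[j]
  which(ok) - 1L
}

#' Longest 3'UTR isoform of a gene
#'
#' When a gene has several annotated 3'UTR isoforms, the longest one (by
#' nucleotide length) is used for seed scanning; ties break to the
#' lexicographically smallest transcript id.
#'
#' @param utrs data.frame with columns `gene_id`, `transcript_id`,
#'   `sequence`.
#' @param gene_id gene to look up.
#' @return list(transcript_id, sequence), or NULL (with a warning) if the
#'   gene has no annotated UTR.
#' @export
longest_utr <- function(utrs, gene_id) {
  u <- utrs[utrs$gene_id == gene_id, , drop = FALSE]
  if (nrow(u) == 0L) {
    warning("gene ", gene_id, " has no annotated 3'UTR; skipped")
    return(NULL)
  }
  u <- u[order(-nchar(u$sequence), u$transcript_id), , drop = FALSE]
  list(transcript_id = u$transcript_id[1], sequence = u$sequence[1])
}

#' Seed-site table for a set of miRNAs against a set of target sequences
#'
#' @param mirnas data.frame: `mirna_id`, `sequence` (and optionally
#'   `regulation`).
#' @param targets data.frame: `target_id`, `sequence`.
#' @return data.frame: mirna_id, target_id, seed, site, n_sites, positions
#'   (comma-separated 0-based offsets).
#' @export
seed_site_table <- function(mirnas, targets) {
  rows <- lapply(seq_len(nrow(mirnas)), function(i) {
    motif <- site_motif(seed_of(mirnas$sequence[i]))
    hits <- lapply(seq_len(nrow(targets)), function(j)
      scan_sites(motif, targets$sequence[j]))
    data.frame(mirna_id = mirnas$mirna_id[i],
               target_id = targets$target_id,
               seed = seed_of(mirnas$sequence[i]),
               site = motif,
               n_sites = lengths(hits),
               positions = vapply(hits, paste, "", collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[out$n_sites > 0L, , drop = FALSE]
}

#' Bipartite miRNA-target network with a minimum-degree rule
#'
#' Pairs regulation directions the way a degradation model predicts:
#' upregulated miRNAs are scanned against downregulated targets, and
#' downregulated miRNAs against upregulated targets. An edge requires at
#' least one exact seed site; a target's degree is its number of distinct
#' miRNA partners (multiple sites for one miRNA still count as degree 1),
#' and only targets with degree >= `min_degree` are retained.
#'
#' @param mirnas data.frame: `mirna_id`, `sequence`, `regulation`
#'   ("up"/"down").
#' @param targets data.frame: `target_id`, `sequence`, `regulation`.
#' @param min_degree minimum number of distinct miRNA partners (default 3).
#' @return list with `edges` (mirna_id, target_id, n_sites; retained targets
#'   only), `degrees` (all targets with >= 1 site) and `sites` (full site
#'   table).
#' @export
build_network <- function(mirnas, targets, min_degree = 3L) {
  stopifnot(all(c("mirna_id", "sequence", "regulation") %in% names(mirnas)),
            all(c("target_id", "sequence", "regulation") %in% names(targets)))
  pair <- function(mdir, tdir) {
    m <- mirnas[mirnas$regulation == mdir, , drop = FALSE]
    t <- targets[targets$regulation == tdir, , drop = FALSE]
    if (nrow(m) == 0L || nrow(t) == 0L) return(NULL)
    seed_site_table(m, t)
  }
  sites <- rbind(pair("up", "down"), pair("down", "up"))
  if (is.null(sites) || nrow(sites) == 0L) {
    empty <- data.frame(mirna_id = character(0), target_id = character(0),
                        n_sites = integer(0))
    return(list(edges = empty,
                degrees = data.frame(target_id = character(0),
                                     degree = integer(0)),
                sites = sites))
  }
  edges <- sites[, c("mirna_id", "target_id", "n_sites")]
  deg <- aggregate(mirna_id ~ target_id, edges,
                   function(x) length(unique(x)))
  names(deg)[2] <- "degree"
  deg <- deg[order(deg$target_id), , drop = FALSE]
  keep <- deg$target_id[deg$degree >= min_degree]
  edges <- edges[edges$target_id %in% keep, , drop = FALSE]
  edges <- edges[order(edges$target_id, edges$mirna_id), , drop = FALSE]
  rownames(edges) <- rownames(deg) <- NULL
  list(edges = edges, degrees = deg, sites = sites)
}
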