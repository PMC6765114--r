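simple_pwm <- function(W = 4L, strong = 0.85) {
  probs <- matrix((1 - strong) / 3, 4L, W)
  cons <- rep_len(c(1L, 3L), W)  # A, G alternating
  for (j in seq_len(W)) probs[cons[j], j] <- strong
  pwm(probs, name = "toy")
}

test_that("MEME minimal round-trip preserves the matrix and background", {
  p <- build_hse_pwm()
  f <- tempfile(fileext = ".meme")
  write_meme(p, f)
  p2 <- read_meme(f)
  expect_equal(p2$probs, p$probs, tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(p2$background, p$background, tolerance = 1e-5)
  expect_equal(p2$width, 15L)
  # the bundled fixture parses to the same motif
  p3 <- read_meme(system.file("extdata", "hse_synthetic_motif.meme",
                              package = "wormhsr"))
  expect_equal(p3$probs, p$probs, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("score_window: identity PWM scores 0, strands mirror", {
  flat <- pwm(matrix(0.25, 4, 3))
  expect_equal(score_window(flat, "ACG"), 0, tolerance = 1e-3)
  p <- simple_pwm(5)
  w <- "AGAGA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(w)))
  expect_equal(score_window(p, w, "+"), score_window(p, rc, "-"))
  # ambiguous base -> NA
  expect_true(is.na(score_window(p, "AGNGA")))
  # W = 1, p(A) ~ 1: score close to log(4)
  p1 <- pwm(matrix(c(1, 0, 0, 0), 4, 1))
  expect_equal(score_window(p1, "A"), log(4), tolerance = 1e-2)
})

test_that("score_pvalue matches exhaustive enumeration for W <= 6", {
  set.seed(21)
  for (W in c(2L, 4L, 6L)) {
    p <- simple_pwm(W, strong = 0.7)
    sch <- wormhsr:::pwm_scheme(p)
    slack <- sch$g * (W + 1)  # discretization tolerance
    for (q in c(0.2, 0.5, 0.9)) {
      s <- q * score_window(p, pwm_consensus(p))
      expect_lte(abs(score_pvalue(p, s) - oracle_pvalue(p, s)),
                 max(oracle_pvalue(p, s - slack) - oracle_pvalue(p, s + slack),
                     1e-12))
    }
  }
})

test_that("score_pvalue handles boundary scores", {
  p <- simple_pwm(3)
  # W = 1 uniform background: p of the single best letter is 0.25
  p1 <- pwm(matrix(c(0.97, 0.01, 0.01, 0.01), 4, 1))
  expect_equal(score_pvalue(p1, score_window(p1, "A")), 0.25)
  # below the minimum attainable score -> 1
  expect_equal(score_pvalue(p, -100), 1)
  expect_error(score_pvalue(p, Inf), "finite")
  # monotone non-increasing in score
  ss <- seq(-2, score_window(p, pwm_consensus(p)), length.out = 25)
  pv <- vapply(ss, function(s) score_pvalue(p, s), numeric(1))
  expect_true(all(diff(pv) <= 1e-12))
})

test_that("scan_genome finds a planted consensus and respects strand symmetry", {
  set.seed(31)
  p <- build_hse_pwm()
  cons <- pwm_consensus(p)
  bg <- paste(sample(c("A", "C"), 4000, TRUE), collapse = "")  # motif-free
  seqs <- c(chrT = paste0(substr(bg, 1, 1000), cons,
                          substr(bg, 1001, 4000)))
  hits <- scan_genome(p, seqs)
  expect_equal(length(hits), 1L)
  expect_equal(start(hits), 1001L)
  expect_equal(as.character(strand(hits)), "+")
  expect_lt(hits$p_value, 1e-4)
  # reverse-complemented genome: same hit, opposite strand, mirrored coords
  rcseq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  names(rcseq) <- "chrT"
  hits_rc <- scan_genome(p, rcseq)
  expect_equal(length(hits_rc), 1L)
  expect_equal(as.character(strand(hits_rc)), "-")
  L <- nchar(seqs[[1]])
  expect_equal(start(hits_rc), L - end(hits) + 1L)
  # impossible threshold -> nothing
  expect_equal(length(scan_genome(p, seqs, p_threshold = 0)), 0L)
})

test_that("summit_regions are 201 bp, centered, clipped at edges", {
  sm <- GRanges("chrI", IRanges(c(5000, 50), width = 1))
  reg <- summit_regions(sm, c(chrI = 100000L))
  expect_equal(c(start(reg)[1], end(reg)[1]), c(4900L, 5100L))
  expect_equal(width(reg)[1], 201L)
  expect_true(mcols(reg)$edge_clipped[2])
  expect_equal(start(reg)[2], 1L)
  # summit BED is 0-based: position 4999 in BED is 1-based 5000
  bed <- tempfile(fileext = ".bed")
  writeLines("chrI\t4999\t5000\ts1\t0\t+", bed)
  reg2 <- summit_regions(bed)
  expect_equal(mcols(reg2)$summit, 5000L)
  expect_equal(c(start(reg2), end(reg2)), c(4900L, 5100L))
})

test_that("classify_bound uses the 14-bp rule on the maximum overlap", {
  reg <- summit_regions(GRanges("chrI", IRanges(c(1000, 1500), width = 1)))
  # regions are [900,1100] and [1400,1600]
  hits <- GRanges("chrI", IRanges(c(887, 888, 1050, 1090), width = 15),
                  strand = c("+", "-", "+", "+"))
  mcols(hits)$score <- 1; mcols(hits)$p_value <- 1e-6
  calls <- classify_bound(hits, reg)
  expect_equal(calls$max_overlap_bp, c(2L, 3L, 15L, 11L))
  expect_equal(calls$bound, c(FALSE, FALSE, TRUE, FALSE))
  # overlap of exactly 14 is bound; 13 is not (already covered above by 15/11);
  h14 <- GRanges("chrI", IRanges(899 - 1, width = 15))   # [898,912] -> 13 bp
  h15 <- GRanges("chrI", IRanges(899, width = 15))       # [899,913] -> 14 bp
  mcols(h14)$score <- mcols(h15)$score <- 1
  mcols(h14)$p_value <- mcols(h15)$p_value <- 1e-6
  expect_false(classify_bound(h14, reg)$bound)
  expect_true(classify_bound(h15, reg)$bound)
  # max over multiple regions: hit overlapping both takes the larger
  wide <- GRanges("chrI", IRanges(1095, 1405))
  mcols(wide)$score <- 1; mcols(wide)$p_value <- 1e-6
  expect_equal(classify_bound(wide, reg)$max_overlap_bp, 6L)
})

test_that("promoter_hse_report counts promoter hits and bound flags", {
  m <- toy_models(list(
    list(id = "gp", chrom = "chrI", strand = "+",
         exons = list(c(5001, 6000))),
    list(id = "gq", chrom = "chrI", strand = "+",
         exons = list(c(20001, 21000)))))
  hits <- GRanges("chrI", IRanges(c(4500, 5500), width = 15))
  mcols(hits)$score <- 1; mcols(hits)$p_value <- 1e-6
  calls <- data.frame(bound = c(TRUE, TRUE))
  rep <- promoter_hse_report(m, hits, calls)
  gp <- rep[rep$gene_id == "gp", ]
  # only the 4500 hit is upstream; the 5500 one is inside the gene body
  expect_equal(gp$n_hse, 1L)
  expect_true(gp$has_bound_hse)
  gq <- rep[rep$gene_id == "gq", ]
  expect_equal(gq$n_hse, 0L)
  expect_false(gq$has_bound_hse)
})
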