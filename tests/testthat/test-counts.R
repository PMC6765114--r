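two_gene_models <- function() {
  toy_models(list(
    list(id = "g1", chrom = "chrI", strand = "+",
         exons = list(c(101, 200), c(301, 400))),
    list(id = "g2", chrom = "chrI", strand = "+",
         exons = list(c(1001, 1200)))))
}

read_gr <- function(s, e, strand = "+", chrom = "chrI") {
  GRanges(chrom, IRanges(s, e), strand = strand)
}

test_that("count_features applies exon precedence and the >=1 bp IJ rule", {
  m <- two_gene_models()
  w <- ij_window(m)
  # g1 window is [91,111]: a read overlapping it by exactly 1 bp
  reads <- list(S_1 = c(
    read_gr(150, 250),   # junction read: exonic for g1, not intronic
    read_gr(201, 290),   # wholly intronic
    read_gr(30, 91),     # 1 bp into g1's IJ window
    read_gr(500, 600)))  # nowhere
  ct <- count_features(reads, m, w, conditions = c(S_1 = "CTRL"))
  cnt <- ct$counts[, 1]
  expect_equal(unname(cnt["g1:exon"]), 1L)
  expect_equal(unname(cnt["g1:intron"]), 1L)
  expect_equal(unname(cnt["g1:ij"]), 1L)
  expect_equal(unname(cnt["g2:exon"]), 0L)
})

test_that("stranded counting requires matching strand", {
  m <- two_gene_models()
  reads <- list(S_1 = read_gr(150, 180, strand = "-"))
  ct <- count_features(reads, m, conditions = c(S_1 = "CTRL"))
  expect_equal(unname(ct$counts["g1:exon", 1]), 0L)
  ct2 <- count_features(reads, m, conditions = c(S_1 = "CTRL"),
                        stranded = FALSE)
  expect_equal(unname(ct2$counts["g1:exon", 1]), 0L + 1L)
})

test_that("reads on unknown chromosomes are skipped with a warning", {
  m <- two_gene_models()
  reads <- list(S_1 = suppressWarnings(
    c(read_gr(150, 180), read_gr(1, 50, chrom = "chrZ"))))
  expect_warning(ct <- count_features(reads, m, conditions = c(S_1 = "CTRL")),
                 "unknown chromosome")
  expect_equal(unname(ct$counts["g1:exon", 1]), 1L)
})

test_that("repeat counting uses primary assignment with lexicographic ties", {
  m <- two_gene_models()
  reps <- GRanges("chrI", IRanges(c(2000, 2050, 3000), c(2099, 2149, 3099)))
  mcols(reps)$name <- c("famB", "famA", "famA")
  reads <- list(S_1 = c(
    read_gr(2000, 2099),  # 100 bp famB vs 50 bp famA -> famB
    read_gr(2045, 2104),  # 55 bp in both -> tie -> famA (lexicographic)
    read_gr(3000, 3050))) # famA only
  ct <- count_features(reads, m, repeats = reps, conditions = c(S_1 = "CTRL"))
  expect_equal(unname(ct$counts["repeat:famA", 1]), 2L)
  expect_equal(unname(ct$counts["repeat:famB", 1]), 1L)
})

test_that("count_features matches the brute-force per-read oracle", {
  set.seed(101)
  for (rep_i in 1:3) {
    n_genes <- 8L
    specs <- lapply(seq_len(n_genes), function(i) {
      s <- 1000L * i
      n_ex <- sample(1:3, 1L)
      ex_s <- s + cumsum(c(0L, rep(250L, n_ex - 1L)))
      list(id = sprintf("g%02d", i), chrom = "chrI",
           strand = sample(c("+", "-"), 1L),
           exons = lapply(seq_len(n_ex), function(j)
             c(ex_s[j], ex_s[j] + sample(80:160, 1L))))
    })
    m <- toy_models(specs)
    w <- ij_window(m)
    n_reads <- 400L
    rs <- sample(1:9500, n_reads, replace = TRUE)
    reads <- GRanges("chrI", IRanges(rs, width = sample(30:120, n_reads, TRUE)),
                     strand = sample(c("+", "-"), n_reads, TRUE))
    ct <- count_features(list(S_1 = reads), m, w,
                         conditions = c(S_1 = "CTRL"))
    orc <- oracle_counts(reads, m, w)
    shared <- intersect(rownames(orc), rownames(ct$counts))
    expect_equal(ct$counts[shared, 1], orc[shared, 1])
  }
})

test_that("size factors follow the median-of-ratios closed form", {
  k <- matrix(c(10, 20, 30, 40,  20, 40, 60, 80), ncol = 2,
              dimnames = list(paste0("g", 1:4), c("a", "b")))
  sf <- size_factors(k)
  # doubling all counts gives factors in ratio 1:2 (geometric mean sqrt(2))
  expect_equal(unname(sf["b"] / sf["a"]), 2)
  expect_equal(unname(sqrt(prod(sf))), 1, tolerance = 1e-12)
  # single sample -> factor 1
  expect_equal(unname(size_factors(k[, 1, drop = FALSE])), 1)
  # identical samples -> equal factors
  sf3 <- size_factors(cbind(k[, 1], k[, 1], k[, 1]))
  expect_true(all(abs(sf3 - sf3[1]) < 1e-12))
  # genes with a zero in any sample are excluded; all-zero usable set errors
  kz <- matrix(c(0, 5, 5, 0), ncol = 2)
  expect_error(size_factors(kz), "pseudocount")
})

test_that("size factors agree with DESeq2's estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(7)
  k <- matrix(rnbinom(600, mu = 60, size = 5), ncol = 6)
  k <- sweep(k, 2, c(1, 1.5, 0.7, 2, 1, 1.2), function(x, y) round(x * y))
  rownames(k) <- paste0("g", seq_len(nrow(k)))
  colnames(k) <- paste0("s", 1:6)
  expect_equal(unname(size_factors(k)),
               unname(DESeq2::estimateSizeFactorsForMatrix(k)),
               tolerance = 1e-8)
})

test_that("fold changes use pseudocounted normalized means", {
  m <- two_gene_models()
  mk <- function(v) read_gr(150, 180)[rep(1, v)]
  reads <- list(CTRL_1 = mk(100), HS_1 = mk(200))
  ct <- count_features(reads, m, conditions = c(CTRL_1 = "CTRL", HS_1 = "HS"))
  sf <- setNames(c(1, 1), names(reads))
  fc <- fold_changes(ct, sf, pseudocount = 0)
  expect_equal(fc$log2fc[fc$feature_id == "g1:exon"], 1)
  # identical conditions -> 0
  fc0 <- fold_changes(ct, sf, ctrl = "CTRL_1", hs = "CTRL_1")
  expect_equal(fc0$log2fc[fc0$feature_id == "g1:exon"], 0)
  # meanCTRL = 0, meanHS = 63, pc = 1 -> log2(64) = 6
  reads2 <- list(CTRL_1 = GRanges(), HS_1 = mk(63))
  ct2 <- count_features(reads2, m, conditions = c(CTRL_1 = "CTRL", HS_1 = "HS"))
  fc2 <- fold_changes(ct2, sf, pseudocount = 1)
  expect_equal(fc2$log2fc[fc2$feature_id == "g1:exon"], 6)
})

test_that("classify_de boundaries are inclusive and symmetric", {
  rec <- data.frame(feature_id = c("a", "b", "c", "d"),
                    baseMean = c(50, 1000, 49.9, 80),
                    log2fc = c(1.0, 0.9, 3, -1.0))
  expect_equal(classify_de(rec, 2, 50, "up"), "a")
  expect_equal(classify_de(rec, 2, 50, "down"), "d")
})

test_that("scaling one sample's counts scales its factor, not fold changes", {
  set.seed(11)
  m <- two_gene_models()
  mk <- function(n) {
    s <- sample(c(101:200, 1001:1200), n, replace = TRUE)
    GRanges("chrI", IRanges(s, width = 50), strand = "+")
  }
  reads <- list(CTRL_1 = mk(300), CTRL_2 = mk(280), HS_1 = mk(500),
                HS_2 = mk(520))
  conds <- c(CTRL_1 = "CTRL", CTRL_2 = "CTRL", HS_1 = "HS", HS_2 = "HS")
  ct <- count_features(reads, m, conditions = conds)
  c_scaled <- ct
  c_scaled$counts[, "HS_1"] <- ct$counts[, "HS_1"] * 3L
  sf1 <- size_factors(ct); sf2 <- size_factors(c_scaled)
  # size factors are defined up to an overall geometric-mean rescaling, so
  # the scaled sample's factor triples relative to any other sample
  expect_equal(unname((sf2["HS_1"] / sf2["CTRL_1"]) /
                        (sf1["HS_1"] / sf1["CTRL_1"])), 3, tolerance = 1e-9)
  f1 <- fold_changes(ct, sf1, pseudocount = 0)
  f2 <- fold_changes(c_scaled, sf2, pseudocount = 0)
  expect_equal(f1$log2fc, f2$log2fc, tolerance = 1e-9)
})
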