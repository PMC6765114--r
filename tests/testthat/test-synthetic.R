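test_that("generate_genome is byte-deterministic under a fixed seed", {
  cfg <- small_sim(7)
  d1 <- tempfile(); d2 <- tempfile()
  b1 <- generate_genome(cfg); b2 <- generate_genome(cfg)
  r1 <- simulate_alignments(b1); r2 <- simulate_alignments(b2)
  write_bundle(b1, r1, d1); write_bundle(b2, r2, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_equal(f1, f2)
  for (f in setdiff(f1, "sim_manifest.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
})

test_that("zero genes still yields a valid empty annotation and a genome", {
  cfg <- sim_config(seed = 1, n_clean_induced = 0L, n_dog_pairs = 0L,
                    n_intron_ncrna = 0L, n_repeat_genes = 0L, n_flat = 0L,
                    n_down = 0L, chrom_length = 5000L)
  b <- generate_genome(cfg)
  expect_equal(length(b$models$genes), 0L)
  expect_equal(sum(nchar(as.character(b$genome))), 5000L)
  d <- tempfile(); write_bundle(b, dir = d)
  expect_equal(length(read_gene_models(file.path(d, "genes.gtf"))$genes), 0L)
})

test_that("an undersized genome raises a sizing error", {
  expect_error(generate_genome(sim_config(seed = 1, chrom_length = 20000L)),
               "cannot be placed")
})

test_that("truth repeat-overlap fractions hit the configured target", {
  for (seed in c(3, 14, 25)) {
    b <- generate_genome(small_sim(seed, repeat_overlap = 0.6))
    f <- b$truth$repeat_overlap_fraction[b$truth$class == "repeat_gene"]
    expect_true(all(abs(f - 0.6) <= 0.05))
    clean <- b$truth$repeat_overlap_fraction[b$truth$class == "clean_induced"]
    expect_true(all(clean <= 0.5))
  }
})

test_that("without readthrough the victim IJ window is condition-balanced", {
  # over 20 simulations, victim IJ counts show no systematic HS/CTRL shift
  diffs <- vapply(1:20, function(seed) {
    cfg <- small_sim(seed, readthrough_fraction = 0)
    b <- generate_genome(cfg)
    reads <- simulate_alignments(b)
    w <- ij_window(b$models, b$chrom_lengths)
    ct <- count_features(reads, b$models, w, conditions = attr(reads, "conditions"))
    vic <- b$truth$gene_id[b$truth$class == "dog_victim"]
    rows <- paste0(vic, ":ij")
    hs <- ct$samples$sample[ct$samples$condition == "HS"]
    ctl <- ct$samples$sample[ct$samples$condition == "CTRL"]
    sum(ct$counts[rows, hs]) - sum(ct$counts[rows, ctl])
  }, numeric(1))
  expect_gt(t.test(diffs)$p.value, 0.01)
})

test_that("strong readthrough drives the victim IJ ratio above 2", {
  hits <- 0L; tot <- 0L
  for (seed in 1:15) {
    res <- run_filter_chain(small_sim(seed))
    tr <- res$bundle$truth
    vic <- tr$gene_id[tr$class == "dog_victim"]
    met <- filter_metrics(vic, res$ct, res$sf, res$bundle$models,
                          res$bundle$repeats, res$windows)
    hits <- hits + sum(met$ij_ratio > 2)
    tot <- tot + length(vic)
  }
  expect_gte(hits / tot, 0.95)
})

test_that("doubling a sample's depth doubles its expected total reads", {
  # compare mean total reads under two depth regimes via the depth attribute:
  # totals scale linearly with the drawn depth factor
  cfg <- small_sim(5, depth_sdlog = 0.4)
  b <- generate_genome(cfg)
  reads <- simulate_alignments(b)
  depth <- attr(reads, "depth")
  totals <- lengths(reads)
  ratio <- totals / depth
  # per-sample reads/depth should be nearly constant (CV much smaller than
  # the depth spread itself)
  expect_lt(stats::sd(ratio[1:3]) / mean(ratio[1:3]), 0.2)
})

test_that("plant_seed_sites yields exactly recoverable counts", {
  set.seed(99)
  mir <- data.frame(mirna_id = c("mA", "mB"),
                    sequence = c("AACGUACGAAAAAAAAAAAAAA",
                                 "AGGGCCCAAAAAAAAAAAAAAA"))
  utrs <- random_utrs(3, 400)
  counts <- data.frame(mirna_id = c("mA", "mA", "mB"),
                       target_id = c("utr1", "utr2", "utr1"),
                       n_sites = c(5L, 0L, 3L))
  ps <- plant_seed_sites(utrs, mir, counts)
  motifA <- site_motif(seed_of(mir$sequence[1]))
  motifB <- site_motif(seed_of(mir$sequence[2]))
  expect_length(scan_sites(motifA, ps$sequences[["utr1"]]), 5L)
  expect_length(scan_sites(motifB, ps$sequences[["utr1"]]), 3L)
  # zero planted on a scrubbed background stays zero
  expect_length(scan_sites(motifA, ps$sequences[["utr2"]]), 0L)
  expect_length(scan_sites(motifA, ps$sequences[["utr3"]]), 0L)
  # recorded positions carry the exact site
  tr <- ps$truth[ps$truth$target_id == "utr1" & ps$truth$mirna_id == "mA", ]
  pos <- as.integer(strsplit(tr$positions, ",")[[1]])
  for (p0 in pos)
    expect_equal(substr(ps$sequences[["utr1"]], p0 + 1, p0 + 6), motifA)
  # two miRNAs in one UTR -> network degree 2 for that target
  net <- build_network(
    transform(mir, regulation = "up"),
    data.frame(target_id = "utr1", sequence = ps$sequences[["utr1"]],
               regulation = "down"),
    min_degree = 2)
  expect_equal(net$degrees$degree, 2L)
  # an impossibly short UTR errors
  expect_error(plant_seed_sites(c(tiny = strrep("A", 30)), mir,
                                data.frame(mirna_id = "mA", target_id = "tiny",
                                           n_sites = 10L)),
               "too short")
})

test_that("plant_hses places bound/unbound instances with exact geometry", {
  set.seed(12)
  p <- build_hse_pwm()
  genome <- DNAStringSet(c(chrS = wormhsr:::random_dna(60000L)))
  pl <- plant_hses(genome, p, n_bound = 5L, n_unbound = 5L)
  expect_equal(sum(pl$truth$bound), 5L)
  expect_equal(sum(!pl$truth$bound), 5L)
  # geometry: overlap with the summit's own 201-bp region matches the record
  reg <- summit_regions(pl$summits)
  for (i in seq_len(nrow(pl$truth))) {
    tr <- pl$truth[i, ]
    if (is.na(tr$summit)) next
    r <- reg[mcols(reg)$summit == tr$summit]
    ov <- overlap_length(GRanges(tr$chrom, IRanges(tr$start, tr$end)),
                         granges(r))
    expect_equal(ov, tr$overlap_bp)
    expect_equal(tr$bound, ov >= 14L)
  }
  # every planted instance is the consensus word in the genome
  cons <- pwm_consensus(p)
  for (i in seq_len(nrow(pl$truth)))
    expect_equal(substr(as.character(pl$genome[["chrS"]]),
                        pl$truth$start[i], pl$truth$end[i]), cons)
})
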