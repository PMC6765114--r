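# -- End-to-end pipeline: simulate -> count -> DE -> filter -> seeds -> HSE -

#' Default heat-shock-element PWM (synthetic)
#'
#' A 15-column PWM emulating the canonical HSE architecture of inverted
#' nGAAn repeats (TTC..GAA..TTC with spacer positions): nine informative
#' columns at probability 0.85 for the consensus base, spacer columns
#' uniform. This is a synthetic stand-in constructed from the published
#' consensus architecture, not a motif discovered from ChIP data.
#'
#' @return A `pwm`.
#' @export
build_hse_pwm <- function() {
  W <- 15L
  probs <- matrix(0.25, 4L, W, dimnames = list(DNA_BASES, NULL))
  cons <- c("T", "T", "C", NA, NA, "G", "A", "A", NA, NA, "T", "T", "C", NA, NA)
  for (j in seq_len(W)) {
    if (!is.na(cons[j])) {
      probs[, j] <- 0.05
      probs[cons[j], j] <- 0.85
    }
  }
  pwm(probs, name = "HSE_synthetic")
}

#' Pipeline configuration
#'
#' Collects all thresholds (defaults are the published values: fold change
#' 2, baseMean 50 for gene classes and 100 for repeat families, IR 0.4 for
#' the DoG rule and 1 for the intronic-ncRNA rule, IJ ratio 2, repeat
#' overlap 0.5, motif p-value 1e-4, 201-bp summit regions, 14-bp bound
#' overlap, 1-kb promoters) together with the simulation config and RNG
#' seed.
#'
#' @param seed integer seed driving every random stage.
#' @param sim a [sim_config()] (seeded from `seed` by default).
#' @param fc_threshold,basemean_min,basemean_min_repeat DE thresholds.
#' @param ir_dog,ij_min,ir_ncrna,repeat_frac filter thresholds.
#' @param p_threshold,region_half_width,min_overlap,promoter_bp HSE stage.
#' @param min_degree miRNA network minimum target degree.
#' @param pseudocount pseudocount for fold changes and IJ ratios.
#' @param stranded strand-aware counting flag.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(seed = seed),
                            fc_threshold = 2, basemean_min = 50,
                            basemean_min_repeat = 100,
                            ir_dog = 0.4, ij_min = 2, ir_ncrna = 1,
                            repeat_frac = 0.5,
                            p_threshold = 1e-4, region_half_width = 100L,
                            min_overlap = 14L, promoter_bp = 1000L,
                            min_degree = 3L, pseudocount = 1,
                            stranded = TRUE) {
  cfg <- as.list(environment())
  thr <- c(cfg$fc_threshold, cfg$basemean_min, cfg$basemean_min_repeat,
           cfg$ir_dog, cfg$ij_min, cfg$ir_ncrna, cfg$repeat_frac,
           cfg$p_threshold, cfg$region_half_width, cfg$min_overlap,
           cfg$promoter_bp, cfg$min_degree, cfg$pseudocount)
  if (any(thr <= 0)) stop("all thresholds must be > 0")
  structure(cfg, class = "pipeline_config")
}

# random miRNA set with pairwise-distinct seeds
random_mirnas <- function(n_up, n_down) {
  repeat {
    seqs <- vapply(seq_len(n_up + n_down), function(i)
      chartr("T", "U", random_dna(22L)), "")
    seeds <- vapply(seqs, seed_of, "")
    if (!anyDuplicated(seeds)) break
  }
  data.frame(mirna_id = sprintf("mir-s%02d", seq_along(seqs)),
             sequence = seqs,
             regulation = rep(c("up", "down"), c(n_up, n_down)),
             stringsAsFactors = FALSE)
}

#' Run the full pipeline on synthetic data
#'
#' Stages: simulate genome and alignments; plant HSEs (two of them into
#' promoters of truly induced genes); count features; size factors; fold
#' changes; up/down classification; readthrough false-positive filter;
#' miRNA seed planting, scanning and network construction; HSE scan, bound
#' classification and promoter report. All stage outputs are written as TSV
#' (plus FASTA/GTF/BED for the simulated inputs) under `out_dir`, with a
#' JSON manifest recording the config, input checksums and per-stage record
#' counts. Identical config and seed reproduce identical stage outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param quiet suppress per-stage log lines.
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  stopifnot(is(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, paste0(...)))
  }

  # -- simulate -------------------------------------------------------------
  bundle <- generate_genome(config$sim)
  models <- bundle$models
  truth <- bundle$truth

  # plant HSEs before writing the genome; direct two bound instances into
  # promoters of truly induced genes
  hse_pwm <- build_hse_pwm()
  set.seed(config$seed + 2L)
  induced <- truth$gene_id[truth$is_truly_induced]
  prom_all <- promoter_windows(models, config$promoter_bp,
                               bundle$chrom_lengths)
  prom_pick <- prom_all[match(utils::head(induced, 2L),
                              mcols(prom_all)$gene_id)]
  planted <- plant_hses(bundle$genome, hse_pwm, n_bound = 5L,
                        n_unbound = 5L, avoid = models$genes,
                        promoters = prom_pick,
                        p_threshold = config$p_threshold)
  bundle$genome <- planted$genome
  reads <- simulate_alignments(bundle)
  paths <- write_bundle(bundle, reads, out_dir)
  rtracklayer::export(planted$summits, file.path(out_dir, "summits.bed"),
                      format = "bed")
  write_tsv(planted$truth, file.path(out_dir, "truth_hse.tsv"))
  log_stage("simulate", length(models$genes), " genes, ",
            sum(lengths(reads)), " reads, ", length(planted$summits),
            " summits")

  # -- count ----------------------------------------------------------------
  windows <- ij_window(models, bundle$chrom_lengths)
  ct <- count_features(reads, models, windows, bundle$repeats,
                       conditions = attr(reads, "conditions"),
                       stranded = config$stranded)
  counts_long <- data.frame(ct$features[rep(seq_len(nrow(ct$features)),
                                            ncol(ct$counts)), ],
                            sample = rep(colnames(ct$counts),
                                         each = nrow(ct$counts)),
                            raw = as.vector(ct$counts))
  sf <- size_factors(ct)
  counts_long$normalized <- counts_long$raw / sf[counts_long$sample]
  write_tsv(counts_long, file.path(out_dir, "counts.tsv"))
  write_tsv(data.frame(sample = names(sf), size_factor = unname(sf)),
            file.path(out_dir, "size_factors.tsv"))
  log_stage("count", nrow(ct$counts), " features x ", ncol(ct$counts),
            " samples")

  # -- fold changes / DE ----------------------------------------------------
  fc <- fold_changes(ct, sf, pseudocount = config$pseudocount)
  write_tsv(fc, file.path(out_dir, "fold_changes.tsv"))
  fc_gene <- fc[fc$type == "exon", ]
  up <- fc_gene$gene_id[fc_gene$feature_id %in%
    classify_de(fc_gene, config$fc_threshold, config$basemean_min, "up")]
  down <- fc_gene$gene_id[fc_gene$feature_id %in%
    classify_de(fc_gene, config$fc_threshold, config$basemean_min, "down")]
  log_stage("de", length(up), " up, ", length(down), " down of ",
            nrow(fc_gene), " genes")

  # -- readthrough filter ---------------------------------------------------
  metrics <- filter_metrics(up, ct, sf, models, bundle$repeats, windows,
                            config$pseudocount)
  filt <- apply_filters(up, metrics, config$ir_dog, config$ij_min,
                        config$ir_ncrna, config$repeat_frac)
  write_tsv(filt$report, file.path(out_dir, "filter_report.tsv"))
  writeLines(filt$kept, file.path(out_dir, "kept_upregulated.txt"))
  writeLines(filt$removed, file.path(out_dir, "removed_upregulated.txt"))
  log_stage("filter", length(filt$removed), " removed, ",
            length(filt$kept), " kept")

  # -- miRNA seeds and network ----------------------------------------------
  set.seed(config$seed + 3L)
  mirnas <- random_mirnas(5L, 5L)
  dn_t <- utils::head(down, 6L)
  up_t <- utils::head(filt$kept, 4L)
  targets <- c(dn_t, up_t)
  seed_truth <- NULL; net <- NULL; site_tab <- NULL
  if (length(targets) > 0L) {
    utrs <- random_utrs(length(targets), 400L, targets)
    up_m <- mirnas$mirna_id[mirnas$regulation == "up"]
    dn_m <- mirnas$mirna_id[mirnas$regulation == "down"]
    plan <- list()
    for (i in seq_along(dn_t)) {
      # first three down-targets get >= 3 up-miRNA partners
      k <- if (i <= 3L) 3L else sample(0:2, 1L)
      if (k > 0L)
        plan[[length(plan) + 1L]] <- data.frame(
          mirna_id = up_m[seq_len(k)], target_id = dn_t[i],
          n_sites = sample(1:3, k, replace = TRUE))
    }
    for (i in seq_along(up_t)) {
      k <- if (i <= 2L) 3L else sample(0:2, 1L)
      if (k > 0L)
        plan[[length(plan) + 1L]] <- data.frame(
          mirna_id = dn_m[seq_len(k)], target_id = up_t[i],
          n_sites = sample(1:3, k, replace = TRUE))
    }
    plan <- if (length(plan)) do.call(rbind, plan) else
      data.frame(mirna_id = character(0), target_id = character(0),
                 n_sites = integer(0))
    ps <- plant_seed_sites(utrs, mirnas, plan)
    seed_truth <- ps$truth
    tdf <- data.frame(target_id = targets,
                      sequence = unname(ps$sequences[targets]),
                      regulation = rep(c("down", "up"),
                                       c(length(dn_t), length(up_t))),
                      stringsAsFactors = FALSE)
    net <- build_network(mirnas, tdf, config$min_degree)
    site_tab <- net$sites
    write_tsv(mirnas, file.path(out_dir, "mirnas.tsv"))
    write_tsv(ps$truth, file.path(out_dir, "truth_seed_sites.tsv"))
    if (!is.null(site_tab)) write_tsv(site_tab,
                                      file.path(out_dir, "seed_sites.tsv"))
    write_tsv(net$edges, file.path(out_dir, "network_edges.tsv"))
    write_tsv(net$degrees, file.path(out_dir, "target_degrees.tsv"))
    log_stage("seeds", nrow(net$edges), " network edges over ",
              length(targets), " targets")
  } else log_stage("seeds", "no DE targets; stage skipped")

  # -- HSE scan -------------------------------------------------------------
  write_meme(hse_pwm, file.path(out_dir, "hse_motif.meme"))
  hits <- scan_genome(hse_pwm, bundle$genome, config$p_threshold)
  regions <- summit_regions(planted$summits, bundle$chrom_lengths,
                            config$region_half_width)
  calls <- classify_bound(hits, regions, config$min_overlap)
  prom_rep <- promoter_hse_report(models, hits, calls, config$promoter_bp,
                                  bundle$chrom_lengths)
  write_tsv(calls, file.path(out_dir, "hse_bound_calls.tsv"))
  write_tsv(prom_rep, file.path(out_dir, "promoter_hse_report.tsv"))
  log_stage("hse", length(hits), " hits, ", sum(calls$bound), " bound")

  # -- manifest -------------------------------------------------------------
  outs <- list.files(out_dir, full.names = TRUE)
  outs <- outs[!grepl("manifest\\.json$", outs)]
  manifest <- list(
    config = lapply(unclass(config), function(x)
      if (is(x, "sim_config")) unclass(x) else x),
    seed = config$seed,
    checksums = as.list(tools::md5sum(sort(outs))),
    records = list(genes = length(models$genes),
                   reads = sum(lengths(reads)),
                   upregulated = length(up), downregulated = length(down),
                   removed = length(filt$removed), kept = length(filt$kept),
                   hse_hits = length(hits), hse_bound = sum(calls$bound)),
    version = as.character(packageVersion("wormhsr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(bundle = bundle, reads = reads, counts = ct, sf = sf,
                 fold_changes = fc, up = up, down = down, filter = filt,
                 mirnas = mirnas, seed_truth = seed_truth, network = net,
                 hse = list(pwm = hse_pwm, hits = hits, regions = regions,
                            calls = calls, promoter_report = prom_rep,
                            truth = planted$truth),
                 manifest = manifest))
}

#' Validate pipeline input files for consistency
#'
#' Checks that the GTF, FASTA and BED inputs parse, that chromosome names
#' agree across files, and that sample condition labels are CTRL/HS.
#'
#' @param gtf,fasta,repeats_bed,reads_beds,summits_bed file paths (any may
#'   be NULL to skip).
#' @param conditions named condition labels for the read samples.
#' @return data.frame of failures (empty when everything is consistent).
#' @export
validate_inputs <- function(gtf = NULL, fasta = NULL, repeats_bed = NULL,
                            reads_beds = NULL, summits_bed = NULL,
                            conditions = NULL) {
  fail <- list()
  note <- function(what, msg)
    fail[[length(fail) + 1L]] <<- data.frame(input = what, problem = msg,
                                             stringsAsFactors = FALSE)
  chroms_ref <- NULL
  if (!is.null(fasta)) {
    fa <- tryCatch(readDNAStringSet(fasta), error = function(e) e)
    if (is(fa, "error")) note("fasta", conditionMessage(fa))
    else chroms_ref <- sub("\\s.*", "", names(fa))
  }
  check_chroms <- function(what, chroms) {
    if (!is.null(chroms_ref) && length(setdiff(chroms, chroms_ref)) > 0L)
      note(what, paste0("chromosome name(s) not in FASTA: ",
                        paste(setdiff(chroms, chroms_ref), collapse = ", ")))
  }
  if (!is.null(gtf)) {
    gm <- tryCatch(read_gene_models(gtf), error = function(e) e)
    if (is(gm, "error")) note("gtf", conditionMessage(gm))
    else check_chroms("gtf", unique(as.character(seqnames(gm$genes))))
  }
  for (nm in c("repeats_bed", "summits_bed")) {
    p <- get(nm)
    if (!is.null(p)) {
      b <- tryCatch(rtracklayer::import(p), error = function(e) e)
      if (is(b, "error")) note(nm, conditionMessage(b))
      else check_chroms(nm, unique(as.character(seqnames(b))))
    }
  }
  if (!is.null(reads_beds)) {
    for (s in names(reads_beds)) {
      b <- tryCatch(rtracklayer::import(reads_beds[[s]]),
                    error = function(e) e)
      if (is(b, "error")) note(paste0("reads:", s), conditionMessage(b))
      else check_chroms(paste0("reads:", s),
                        unique(as.character(seqnames(b))))
      if (!is.null(conditions) &&
          (is.na(conditions[s]) || !conditions[s] %in% c("CTRL", "HS")))
        note(paste0("reads:", s), "missing or invalid condition label")
    }
  }
  if (length(fail) == 0L)
    return(data.frame(input = character(0), problem = character(0)))
  do.call(rbind, fail)
}
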