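Package: wormhsr
Title: Heat-Shock Transcriptome Filtering and Regulatory Analysis for Compact Genomes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for analysing heat-shock (HS) induced
    transcriptome changes in compact genomes such as Caenorhabditis elegans.
    Implements a false-positive filter for HS-upregulated protein-coding genes
    that removes artifacts caused by transcriptional readthrough
    (downstream-of-gene, DoG, transcripts), intron-resident non-coding RNAs and
    repeat overlap; median-of-ratios depth normalization with fold-change and
    baseMean classification; miRNA seed-site scanning of 3'UTRs with bipartite
    target-network construction; and position-weight-matrix scanning for heat
    shock elements (HSEs) with exact p-values, 201-bp ChIP summit regions and a
    bound-HSE classifier. Includes a synthetic-data generator with planted
    ground truth (negative-binomial counts, exponentially decaying readthrough
    tails, intronic small-RNA signal, planted seed sites and motif instances)
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
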