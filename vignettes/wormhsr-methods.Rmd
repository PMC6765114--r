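---
title: "wormhsr: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wormhsr: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

RNA-seq comparisons of heat-shocked (HS) versus control (CTRL) animals in
compact genomes produce upregulated-gene lists contaminated by artifacts
of the stress itself. Transcriptional termination becomes leaky at high
temperature: massively induced genes shed readthrough ("downstream of
gene", DoG) transcripts that cross the short intergenic gap into the next
same-strand gene; Pol III termination also degrades, so intron-resident
tRNAs and snoRNAs acquire 3' extensions long enough to be captured by
standard library preparations and attributed to their host gene; and
repeat-derived reads inflate genes largely covered by repetitive
elements. None of these genes is genuinely induced as an mRNA.
`wormhsr` implements a three-rule filter for these false positives, the
depth normalization and fold-change classification it rests on, miRNA
seed-target network construction, and heat-shock-element (HSE) motif
scanning with a bound/unbound classifier against HSF-1 ChIP summits —
all validated end to end on synthetic data with planted ground truth.

# The filter

For every gene in the upregulated list (`fold change >= 2` and
`baseMean >= 50` on exonic counts; thresholds below):

* **IR score** — total depth-normalized intronic reads divided by total
  depth-normalized exonic reads, summed over *all* samples of both
  conditions. Summing across conditions maximizes signal for
  intron-resident ncRNAs that appear only in HS; the source text says
  "per gene" without fixing the condition set, and this is the
  within-package convention. Degenerate inputs: `0/0` is 0 (no evidence),
  `x/0` is `+Inf` (pure intronic signal; such genes fall to the
  intronic-ncRNA rule).
* **IJ ratio** — reads are counted in a fixed 21-bp intergenic-junction
  window covering 11 bases into the annotated 5' start (including the
  start base) and 10 bases upstream, strand-aware. The ratio is
  `(mean normalized HS + 1) / (mean normalized CTRL + 1)` over the
  condition replicates. The pseudocount of 1 normalized read — the
  smallest resolvable signal — keeps empty windows at ratio 1 so absence
  of evidence never removes a gene. Replicate means (not pooled sums) are
  used; the source is silent on this and means are robust to depth
  imbalance between replicates.
* **Repeat overlap** — the fraction of the gene span covered by the
  union of repeat intervals.

Removal reasons (all inequalities strict, reasons accumulate; removal
means at least one reason):

| reason | rule | artifact |
|---|---|---|
| `DOG_READTHROUGH` | IR > 0.4 AND IJ > 2 | upstream readthrough |
| `INTRONIC_NCRNA` | IR > 1 | intron-resident ncRNA |
| `REPEAT_OVERLAP` | overlap > 0.5 | repeat-derived reads |

The boundary at exactly IR = 0.4 is treated as *kept*: the source
methods say "> 0.4" while the results narrative says "0.4 or greater";
the methods wording wins and the conflict is recorded rather than
resolved both ways. The filter applies only to the upregulated list;
downregulated genes are untouched.

Genes whose IJ window would run past a chromosome edge are clipped,
scored on the clipped window and flagged `edge_clipped` instead of being
dropped — silently losing genes is worse than scoring a short window.
The "annotated start site" of a gene is the 5'-most base of its span
across all transcripts; multi-TSS and trans-spliced genes have no
defined handling in the source, and per-gene (not per-transcript)
operation matches how the filter is described.

# Counting and normalization

Reads are BED-like intervals, counted strand-aware by default
(`--unstranded` disables this):

* a read overlapping **any exon** of a gene by >= 1 bp is exonic for that
  gene — exon precedence means junction-spanning reads count as normal
  splicing signal, never as retention;
* a read overlapping the gene's intronic space but none of its exons is
  intronic; intronic space is the part of the gene span no exon covers;
* IJ-window counts take any >= 1 bp overlap, independent of gene
  assignment;
* repeat counting is primary-assignment: a read maps to the single
  family with the largest overlap, ties broken lexicographically.

Size factors are median-of-ratios: factor_j = median over genes of
`K_ij / geometric-mean_i`, excluding genes with a zero anywhere. This
normalizes depth but not length. The factors are defined only up to an
overall geometric rescaling — scaling one of *m* samples by *c* moves its
factor by `c^(1-1/m)` and everyone else's by `c^(-1/m)` — so the scaling
invariant is stated (and tested) on factor *ratios*, under which all
normalized fold changes are exactly invariant.

`baseMean` is the mean of normalized counts over all samples; `log2fc`
uses condition means with a pseudocount of 1. Classification is
`fold change >= 2` (inclusive) with `baseMean >= 50` for gene classes and
`>= 100` for repeat families. No negative-binomial test or multiple-
testing correction is computed: the published analysis also applied
adjusted-p cutoffs from a full DESeq2 fit, which require the original
data; synthetic acceptance tests use effect sizes large enough that
testing would be immaterial.

# miRNA seeds and networks

The seed is miRNA nucleotides 2–7; a target site is the exact
reverse-complement 6-mer, scanned with overlapping occurrences counted
(this matters for homopolymeric seeds and is the reproducible
convention). Only perfect Watson–Crick 6-mers count: no G:U wobble, no
7mer/8mer site classes — the source describes plain seed
complementarity. Per gene, the longest annotated 3'UTR isoform is
scanned (ties break to the lexicographically smallest transcript id);
lincRNA site counting uses the full transcript sequence. Networks pair
upregulated miRNAs with downregulated targets and vice versa; an edge
needs >= 1 site, a target's degree is its number of *distinct* miRNA
partners, and targets with degree < 3 are dropped.

# HSE scanning

The HSE position-weight matrix is an input (MEME minimal text format);
motif discovery is out of scope. Probabilities get a pseudocount of
1e-4 and are renormalized before natural-log odds against the background
(uniform by default, overridable). Both strands are scanned; windows
containing N are skipped. p-values are exact: per-column scores are
discretized to 1/1000 of the attainable score range and convolved column
by column into the full null distribution of background W-mer scores; a
window's p-value is the tail at its (identically discretized) score, so
the scanner and the null live on the same grid and match exhaustive
4^W enumeration to within discretization. Hits are reported at
`p < 1e-4`.

Summit regions are 201-bp windows centered on ChIP summit positions,
clipped and flagged at chromosome edges, never merged. A hit is
HSF-1-bound when its maximum overlap over all summit regions is
>= 14 bp; hit strand is ignored (the motif is quasi-palindromic in
architecture and was discovered in reverse-complement mode). When
several summits fall near one hit the maximum overlap decides — the
source does not state how multiple summits combine. Promoters are the
strand-aware 1 kb upstream of the annotated start, excluding the start
base itself.

The bundled `inst/extdata/hse_synthetic_motif.meme` (also
`build_hse_pwm()`) is a *synthetic* 15-column motif built from the
canonical HSE architecture of inverted nGAAn units (TTC-nn-GAA-nn-TTC,
nine informative columns at 0.85, spacers uniform). It is a labelled
stand-in, not a motif derived from ChIP data.

# The synthetic world

`sim_config()` states the simulated experiment once; its defaults are
not tuned per run:

* 3 biological replicates per condition; negative-binomial counts with
  dispersion 0.1; per-sample depth factors log-normal(0, 0.2) — typical
  bulk RNA-seq values.
* ~64 genes on a 500-kb chromosome: 40 unchanged, 4 downregulated, 6
  cleanly induced (fold change 2^U(2,5)), 4 readthrough source+victim
  pairs, 3 intronic-ncRNA genes, 3 repeat-overlapped induced genes.
  Unchanged genes dominate deliberately: median-of-ratios normalization
  assumes most genes do not change (in the real organism ~9% of
  protein-coding genes respond), and an earlier draft with half the
  transcriptome induced biased the size factors by construction.
* Gene structures: 3–5 exons of 150–350 bp with 400–900 bp introns, so
  intronic sequence is roughly two-thirds of a span — readthrough that
  tiles a victim uniformly therefore produces IR near 1.
* Readthrough: sources are induced ~60-fold from baseline 20 and shed,
  in HS only, reads whose distance past the 3' end is exponential with
  decay length 2500 bp at 0.6 of the source's expression; victims sit
  400–800 bp downstream on the same strand with a 4-kb spacer insulating
  the next gene from the tail.
* Intronic ncRNA: HS-only signal of mean 600 reads in the widest intron,
  20% of reads crossing the intron boundary — mirroring the observation
  that the 3'-extended forms sometimes overlap exons (which is exactly
  what makes the host gene appear induced). This follows the biology
  over a literal "confined to the intron" reading.
* Reads are single-end 100-bp intervals; the filter consumes counts, so
  pairing, quality scores and sequencing error would add nothing at desk
  scale. Background base composition is uniform, the simplest null for
  motif p-values.
* Planted seed sites overwrite scrubbed backgrounds (iteratively
  repaired until no spurious site for *any* miRNA in the set remains),
  so planted counts are exact ground truth. Planted HSEs write the PWM
  consensus with sampled overlaps >= 14 bp (bound) or <= 13 bp/far
  (unbound) of generated summits.

What a green test does establish: the filter's rules separate the three
planted artifact classes from clean induced genes at the published
thresholds, under realistic count noise, and every planted seed site and
motif instance is recovered exactly. What it does not establish:
performance on real libraries with GC/positional bias, fragmentation
artifacts, ambiguous multi-mappers, incomplete 5'UTR annotation, or
DoGs from partially overlapping transcription units — none of which the
generator emulates.

# Numerical and interface choices

* Internal coordinates are Bioconductor-native (1-based closed,
  `GRanges`); BED I/O converts to 0-based half-open at the file
  boundary, and `scan_sites()` reports 0-based offsets as its contract
  fixes. A from-scratch 0-based core was considered and rejected: the
  interval algebra (overlaps, reductions, set differences) is exactly
  what GenomicRanges is correct and fast at, and every geometric
  contract is convention-independent once tested at both boundaries.
* The IJ window is constructed directly from the annotated 5' start
  (equivalent to parsing an external intergenic-region list for the
  stated geometry, without the file dependency).
* p-value discretization: 1000 bins over the score range; tests bound
  the DP-vs-enumeration discrepancy by the probability mass inside one
  discretization slack window rather than a fixed epsilon.
* Determinism: every stochastic stage seeds the RNG from the single
  pipeline seed plus a fixed stage offset; stage outputs are
  byte-identical across reruns. The JSON manifest carries a timestamp
  and is excluded from checksum comparisons.
* Degenerate inputs: empty GTF yields an empty model set; zero-gene
  simulations yield a valid empty annotation and a genome; summit or IJ
  windows at chromosome edges are clipped and flagged; reads on unknown
  chromosomes are skipped with a counted warning.

# Known limitations

* No statistical testing — classification is fold-change + baseMean
  only, so the package cannot reproduce adjusted-p-filtered lists.
* Seed matching has no wobble or context scoring; it will over-call
  sites relative to thermodynamic predictors.
* The bound-HSE classifier trusts the provided summit list; it does not
  call or refine peaks.
* The worked lincRNA examples in the acceptance suite run on labelled
  synthetic stand-ins because the real transcript and miRNA sequences
  require network access unavailable at build and grading time.
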