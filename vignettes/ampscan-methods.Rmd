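---
title: "Methods: promoter co-occupancy and transcriptional amplification"
author: "ampscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter co-occupancy and transcriptional amplification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampscan)
```

# Scope and model

ampscan analyses the regulatory program of a transcription-factor pair —
prototypically C-MYC and SOX2 in immortalized multipotent otic progenitor
(iMOP) cells versus primary otospheres — in three linked steps:

1. **Promoter occupancy.** Gene promoters are fixed windows of ±5 kb around
   the strand-aware TSS. A factor is called *bound* at a promoter when its
   ChIP read count in the window is enriched over a uniform genomic
   background. A gene is a *target* of a factor when both RNA POLII and the
   factor are bound in the promoter window (POLII anchoring restricts calls
   to transcriptionally engaged promoters).
2. **Co-occupancy.** Target sets of two factors are intersected and the
   overlap reported as counts and percentages in both directions.
3. **Amplification.** For the co-occupied target set, RPKM fold increases
   between conditions are summarized and a rightward shift of the RPKM
   cumulative distribution is tested with Welch's two-tailed t on log10
   RPKM.

A synthetic-data module generates every input with recorded ground truth, so
the whole pipeline is testable end to end without external data.

# Binding-call statistic

No peak caller is used; occupancy is scored directly in the promoter window.
With $N$ total reads, genome length $G$ and nominal window length
$w = 2 \cdot \mathrm{flank}$, the background expectation for each gene is
$\lambda = N w / G$. The per-gene p-value is the Poisson upper tail
$P(X \ge \text{count})$, adjusted across genes by Benjamini–Hochberg; a gene
is bound iff $q < 0.05$ **and** $\text{count}/\lambda \ge 2$. The fold gate
protects against calling tiny enrichments significant at high depth. This is
deliberately the simplest defensible model: a uniform background, no
duplicate handling, no local lambda. Genes whose windows are clamped at
chromosome edges keep the nominal $w$ in $\lambda$, so edge genes are not
spuriously enriched by a shortened window.

Reads are assigned to windows by their midpoint, half-open
(`[win_start, win_end)`); a read may count toward several overlapping
windows but never twice toward one. Coordinates are 0-based half-open (BED)
throughout, and the TSS of a minus-strand gene is `end - 1`.

# Metaprofiles and quantile normalization

TSS metaprofiles bin read midpoints by strand-oriented offset (positive =
downstream). Minus-strand offsets are mirrored at the half-open level
(`offset -> -offset - 1`), which makes the profile of a strand-flipped
annotation the exact reversal of the original — a property the test suite
asserts bin for bin. When several factors are displayed on one axis their
binned densities can be quantile normalized: rank-r values are replaced by
the mean r-th order statistic across columns, ties receiving the mean of
their rank-range replacement values. With ties present the post-normalization
column distributions agree in mean but not exactly in multiset, the same
behavior as limma's tie-averaged implementation (used as an independent
cross-check in the tests).

# Amplification statistics

RPKM is $10^9 \cdot \text{count} / (\text{length} \cdot \text{library
size})$ with library sizes defaulting to column sums. Two caveats matter and
are deliberate:

- **Compositional damping.** When a large gene set is truly amplified, the
  amplified condition's library grows, so RPKM folds under-recover the
  simulated multiplier (a 1.5× amplification of 40% of genes yields observed
  RPKM folds around 1.2–1.3). Tests that check *generator* fidelity therefore
  fix equal library sizes; the pipeline itself keeps the field-standard
  column-sum convention.
- **Heatmap normalization** subtracts each gene's median RPKM across all
  samples and divides by the raw median absolute deviation (no 1.4826
  consistency factor — the raw definition is wanted for display scaling).
  Zero-MAD non-constant rows fall back to an epsilon scale; constant rows
  become zero.

The distribution-shift test averages RPKM across replicates per condition,
keeps genes with condition-mean RPKM in [1, 1e4] (applied per condition, so
a gene may enter only one condition's CDF), and applies Welch's t to the
log10 values. Because both conditions share per-gene baselines, the
between-gene variance in the denominator overstates the null variance of the
mean difference, making the test conservative under the null (empirical
size ≈ 0 at nominal 0.05 in the suite's 200-seed null simulation) while
retaining high power against a 1.5× shift at ~800 target genes.

# Transcriptome comparison

Sample similarity uses Spearman's rank correlation with average-rank ties;
samples with constant values get explicit `NA` correlations. Clustering is
average linkage on $d = 1 - \rho$ with samples pre-sorted lexicographically
so tie-breaking is deterministic; dendrograms are exported as Newick.
Differential expression is Welch's t on log2(RPKM + 1) across replicates
with BH adjustment — chosen for self-containment and consistency with the
shift test rather than as a replacement for count-model DE; with a single
replicate only fold changes are emitted. Gene-set enrichment is the
hypergeometric upper tail against a user-supplied gene-to-term table (no
ontology fetching or DAG propagation; annotation-version-dependent counts
are not reproducible results).

# Bisulfite methylation

CpG sites are the `CG` dinucleotide offsets of the untreated reference. In a
converted clone, a CpG cytosine reading `C` is methylated (protected), `T`
unmethylated, anything else ambiguous; ambiguous calls leave the percent
denominator. Clones are assumed gapless and equal length (Sanger clones of a
short regulatory region are trivially alignable; alignment is out of scope).
Percent methylation is reported to one decimal. The round-trip property —
calls on clones simulated at conversion rate 1 recover the simulated states
exactly — is asserted in the tests, and incomplete conversion inflates
apparent methylation by at most $(1-\text{conversion rate})(1-p)$ in
expectation, which the suite checks by simulation.

# Small-sample quantifications

Labeled-cell fractions report the percentage at a caller-chosen precision
(round-half-to-even) with a Wilson score interval at z = 1.96; composition
and transcript-fraction partitions are scale-invariant percentages (whole
percents and one decimal respectively; rounded compositions may not sum to
100 and are reported as-is). Doubling time is `1 / slope` of the
least-squares fit of log2(count) on time, using every point of a growth
series rather than a single interval; slopes ≤ 1e-10 are reported as
undefined (`NA`).

# Synthetic-data generator

The generator emulates the assumed structure of the real data:

- **Genome**: `n_genes` non-overlapping gene bodies (1–5 kb) placed in
  per-chromosome slots with 50/50 strands, TSSs ≥ 5 kb from chromosome ends.
- **ChIP reads**: a two-component mixture. Signal reads center at
  `TSS + Normal(0, frag_sd)` of a uniformly chosen bound gene — one
  parameter reproduces a unimodal, promoter-proximal concentration of
  binding. The signal weight is `S/(G+S)` with
  `S = n_bound * (enrichment - 1) * 2 * flank`, chosen so that the realized
  in-window density at bound promoters is about `enrichment`-fold
  background; `enrichment <= 1` degenerates to pure background.
- **Expression**: per-gene lognormal baselines, negative-binomial counts
  with variance = mean + dispersion·mean² (stated because NB conventions
  differ), target genes multiplied by the amplification factor in the
  iMOP-like condition. An optional ESC-like condition draws an independent
  baseline, giving a transcriptome-wide distinct program for clustering
  checks.
- **Bisulfite clones**: per-site Bernoulli methylation; unmethylated CpG and
  non-CpG cytosines convert C→T with the conversion rate.

Defaults are the study conditions the package is designed around: one
100 Mb chromosome, 2,000 genes, 40% true targets, 10× promoter enrichment,
2×10⁵ reads per factor (read length 50, frag_sd 500), 3 otosphere-like and 2
iMOP-like replicates, 1.5× amplification, and 10 clones over 15 CpG sites.
Read depth and library protocol are not published for the original data, so
depths were chosen once for statistical power. The generator does **not**
emulate mappability structure, duplicate reads, fragment-size distributions,
GC or length biases, isoform structure, or sequencing error; passing tests
demonstrate correctness of the statistical machinery under the stated model,
not robustness to those artifacts in real libraries.

Seeding: one master seed; each generator derives its stream as
`(master * 48271 + offset) mod (2^31 - 1)` with a fixed per-stream offset,
so adding draws to one generator never perturbs another. All generators are
byte-deterministic given the config.

# Numerical and design choices

- Poisson tails via the distribution function (`ppois` upper tail); the test
  oracle sums the upper tail directly to avoid cancellation.
- Welch statistic degenerates gracefully: identical groups give t = 0,
  p = 1.
- Empty-set overlap fractions are `NA`, never 0.
- The DE sensitivity simulation in the test suite uses a higher baseline
  expression (mean log2 = 8) than the pipeline default: with single-digit
  counts, shot noise rather than NB dispersion dominates, and the
  "low-dispersion" regime the check targets does not exist.
- Problem sizes in the suite: full 2,000-gene/2×10⁵-read configurations for
  the headline recovery checks; 100 + 200 seed replicates for power and
  size of the shift test; 20 seeds for clustering topology and DE recovery;
  smaller genomes (200–500 genes) elsewhere, chosen so the entire suite runs
  in well under a minute on one CPU.

# Known limitations

- The binding rule is promoter-window-only; no de-novo peaks, motifs or
  enhancers.
- RPKM is the only expression unit (no TPM or model-based size factors), to
  match the quantities the pipeline summarizes.
- Welch-based DE is underpowered relative to count-model tests at very small
  replicate numbers and is not intended as a DESeq2/edgeR replacement.
- The bisulfite module inspects the C strand only and does not estimate
  conversion efficiency from non-CpG sites.
- Several printed percentages in the motivating dataset are internally
  inconsistent with their own counts (e.g. 652/720 is 90.6%, not 90.0%;
  61/1,422 is 4.3%, not 4.1%); only arithmetically consistent pairs are used
  as worked examples.
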