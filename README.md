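# ampscan

Promoter co-occupancy and transcriptional amplification analysis for
ChIP-seq and RNA-seq.

## The problem

In stem and progenitor biology, a transcription factor can act as an
*amplifier* of an existing program rather than a switch: C-MYC binds the
promoters already occupied by RNA polymerase II and a lineage factor (here
SOX2, in immortalized multipotent otic progenitor — iMOP — cells) and
multiplicatively boosts their output. Detecting this requires three linked
analyses that this package implements as a tested, reusable pipeline:

1. **POLII-anchored target calling.** Promoters are ±5 kb windows around the
   strand-aware TSS. For each factor, the window read count is tested
   against the uniform background expectation λ = N·w/G with a Poisson
   upper-tail test, BH-adjusted across genes; a gene is bound iff q < 0.05
   and count/λ ≥ 2. A gene is a *target* of a factor iff both POLII and the
   factor are bound in its promoter.
2. **Co-occupancy.** Target-set overlap counts and percentages (e.g. the
   fraction of SOX2 targets whose promoters are also occupied by C-MYC),
   plus quantile-normalized TSS metaprofiles of binding density.
3. **Amplification.** Per-gene RPKM fold increases across conditions,
   median/MAD row normalization for heatmap display, and a
   cumulative-distribution shift test: Welch's two-tailed t on log10 RPKM of
   the target set, genes filtered to 1–10⁴ RPKM per condition.

Supporting modules cover transcriptome comparison (Spearman correlation,
average-linkage clustering, Welch-based differential expression,
hypergeometric gene-set enrichment), bisulfite clone methylation analysis of
a regulatory region (CpG calls, lollipop matrices, percent methylation), and
small-sample quantifications (labeled-cell fractions with Wilson intervals,
composition, transcript partitioning, growth-curve doubling time). A
synthetic-data module generates every input — annotation, ChIP reads,
NB counts, bisulfite clones — with recorded ground truth.

See `vignettes/ampscan-methods.Rmd` for the statistical model, parameter
defaults, and what the simulations do and do not emulate.

## Worked example

```r
library(ampscan)

cfg   <- sim_config(seed = 42)          # 2,000 genes, 2e5 reads/factor, 1.5x amplification
ann   <- simulate_genome(cfg)
truth <- simulate_ground_truth(ann, cfg)
win   <- build_tss_windows(ann, flank = 5000)

occ <- do.call(rbind, lapply(c("POLII", "CMYC", "SOX2"), function(f) {
  rs <- simulate_chip_reads(ann, truth, cfg, f)
  call_binding(count_window_reads(win, rs), rs, win, sum(cfg$chrom_sizes))
}))
sox2 <- call_targets(occ, "SOX2")
cmyc <- call_targets(occ, "C-MYC")
ov   <- overlap_stats(sox2, cmyc)

em    <- simulate_expression(ann, truth, cfg)
co    <- intersect(sox2, cmyc)
shift <- cdf_shift_test(em, co)
fs    <- fold_summary(rpkm(em, library_sizes = rep(1e6, 5)), co)
```

Printed results (seed 42):

```
SOX2 targets: 804  C-MYC targets: 802  shared: 802 (99.8% of SOX2)
CDF shift: t = 3.19, df = 1592, p = 1.44e-03
fold increase: max 16.5, mean 1.63, median 1.50
SOX2-labeled: 92% (95% CI 90.5-93.8)
```

Reading: of 2,000 simulated genes, 800 are true POLII+SOX2+C-MYC targets;
the calls recover them with near-perfect sensitivity and precision, so the
two target sets overlap almost completely. The iMOP-like condition's log10
RPKM distribution of the co-occupied targets is significantly right-shifted
(positive t), and the median per-gene fold recovers the simulated 1.5×
multiplier when library sizes are held equal (with column-sum library sizes
the folds are compositionally damped — see the vignette). The last line is
`labeled_fraction(956, 1036)`: a labeled-cell percentage with its Wilson
interval. `run_full(cfg, out_dir = "...")` executes the same stages and
writes BED/TSV/JSON outputs plus a run report.

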