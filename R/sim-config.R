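#' Simulation configuration
#'
#' Bundles every tunable parameter of the synthetic-data generators into one
#' validated object. Defaults reproduce the study conditions the package is
#' designed around: one 100 Mb chromosome carrying 2,000 genes, ChIP libraries
#' of 2e5 single-end 50 bp reads per factor with 10-fold promoter enrichment
#' at bound genes, negative-binomial RNA-seq counts for 3 otosphere-like and
#' 2 iMOP-like replicates with a 1.5-fold amplification of target genes in the
#' iMOP-like condition, and bisulfite clone sequencing of 10 clones over a
#' region with 15 CpG sites.
#'
#' @param chrom_sizes named numeric vector, chromosome name -> length (bp).
#' @param n_genes number of genes to simulate.
#' @param seed master seed; every generator derives its own reproducible
#'   sub-stream from it (see [derive_seed()]).
#' @param chip_enrichment fold read-density enrichment over the uniform
#'   background at bound promoters. Values <= 1 give pure background.
#' @param chip_reads_per_factor total reads emitted per ChIP factor.
#' @param read_length read length in bp.
#' @param frag_sd standard deviation (bp) of bound-read centers around the TSS.
#' @param target_fraction fraction of genes that are true co-occupancy targets
#'   (bound by POLII and both factors).
#' @param polii_extra_fraction,factor_extra_fraction additional fractions of
#'   genes bound only by POLII, or only by one transcription factor, so that
#'   the bound sets are strict supersets of the target set.
#' @param expr_mean_log2 mean of the per-gene baseline log2 expression level.
#' @param expr_sd_log2 SD of the per-gene baseline log2 expression level.
#' @param expr_dispersion negative-binomial dispersion; the parameterization is
#'   variance = mean + dispersion * mean^2.
#' @param amplification_factor multiplicative factor applied to target-gene
#'   means in the iMOP-like condition.
#' @param n_replicates named integer vector with elements `otosphere` and
#'   `imop`.
#' @param gene_length_range integer range (bp) gene body lengths are drawn from.
#' @param flank promoter half-width in bp; also the footprint used to weight
#'   the ChIP signal component.
#' @param bisulfite list with `site_meth_probs` (per-CpG methylation
#'   probabilities), `n_clones`, and `conversion_rate` in (0, 1].
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(chrom_sizes = c(chr1 = 1e8),
                       n_genes = 2000,
                       seed = 1L,
                       chip_enrichment = 10,
                       chip_reads_per_factor = 2e5,
                       read_length = 50,
                       frag_sd = 500,
                       target_fraction = 0.4,
                       polii_extra_fraction = 0.2,
                       factor_extra_fraction = 0.1,
                       expr_mean_log2 = 4,
                       expr_sd_log2 = 2,
                       expr_dispersion = 0.05,
                       amplification_factor = 1.5,
                       n_replicates = c(otosphere = 3, imop = 2),
                       gene_length_range = c(1000, 5000),
                       flank = 5000,
                       bisulfite = list(site_meth_probs = rep(0.8, 15),
                                        n_clones = 10,
                                        conversion_rate = 1)) {
  stopifnot(length(chrom_sizes) >= 1, !is.null(names(chrom_sizes)),
            all(chrom_sizes > 0))
  if (n_genes < 0) stop("n_genes must be >= 0")
  if (chip_enrichment < 0) stop("chip_enrichment must be non-negative")
  if (expr_dispersion <= 0) stop("expr_dispersion must be positive")
  if (amplification_factor <= 0) stop("amplification_factor must be positive")
  stopifnot(target_fraction >= 0, target_fraction <= 1,
            target_fraction + polii_extra_fraction +
              2 * factor_extra_fraction <= 1)
  stopifnot(all(c("otosphere", "imop") %in% names(n_replicates)),
            all(n_replicates >= 1))
  bp <- bisulfite$site_meth_probs
  stopifnot(all(bp >= 0), all(bp <= 1),
            bisulfite$conversion_rate > 0, bisulfite$conversion_rate <= 1)
  structure(list(chrom_sizes = chrom_sizes, n_genes = as.integer(n_genes),
                 seed = as.integer(seed), chip_enrichment = chip_enrichment,
                 chip_reads_per_factor = as.integer(chip_reads_per_factor),
                 read_length = as.integer(read_length), frag_sd = frag_sd,
                 target_fraction = target_fraction,
                 polii_extra_fraction = polii_extra_fraction,
                 factor_extra_fraction = factor_extra_fraction,
                 expr_mean_log2 = expr_mean_log2, expr_sd_log2 = expr_sd_log2,
                 expr_dispersion = expr_dispersion,
                 amplification_factor = amplification_factor,
                 n_replicates = n_replicates,
                 gene_length_range = as.integer(gene_length_range),
                 flank = as.integer(flank), bisulfite = bisulfite),
            class = "sim_config")
}

# Fixed stream offsets; one Lehmer-style step keeps sub-seeds stable, distinct
# across streams, and below 2^31 - 1.
.stream_offsets <- c(genome = 1L, truth = 2L, chip_POLII = 3L, chip_CMYC = 4L,
                     chip_SOX2 = 5L, expression = 6L, bisulfite = 7L,
                     growth = 8L)

#' Derive a reproducible sub-seed for a named simulator stream
#'
#' Each generator seeds its own RNG stream with
#' `(master * 48271 + offset) mod (2^31 - 1)` where `offset` is a fixed
#' per-stream constant, so changing one generator's draw count never perturbs
#' another generator run under the same master seed.
#'
#' @param master integer master seed.
#' @param stream one of `"genome"`, `"truth"`, `"chip_POLII"`, `"chip_CMYC"`,
#'   `"chip_SOX2"`, `"expression"`, `"bisulfite"`, `"growth"`.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stream) {
  off <- .stream_offsets[[match.arg(stream, names(.stream_offsets))]]
  s <- (as.numeric(master) %% 2147483647) * 48271 + off
  as.integer(s %% 2147483647) + 1L
}
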