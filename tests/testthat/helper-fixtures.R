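# Small, fast configurations used across tests. The full-size study
# conditions (2,000 genes, 2e5 reads/factor) appear only where a check is
# about those conditions.

small_config <- function(seed = 1L, ...) {
  sim_config(chrom_sizes = c(chr1 = 2e7), n_genes = 300,
             chip_reads_per_factor = 2e4, seed = seed, ...)
}

# annotation with hand-picked genes on one chromosome
toy_annotation <- function(chrom_len = 1e6) {
  genome_annotation(gene_id = c("gA", "gB", "gC"),
                    chrom = "chr1",
                    start = c(10000, 40000, 70000),
                    end = c(20000, 50000, 80000),
                    strand = c("+", "-", "+"),
                    chrom_sizes = c(chr1 = chrom_len))
}

# expression matrix with explicit values, 2 conditions
toy_expression <- function(values, lengths = rep(1000, nrow(values)),
                           condition = c("otosphere", "otosphere",
                                         "imop", "imop")) {
  rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  colnames(values) <- paste0(condition, "_", seq_along(condition))
  expression_matrix(values, lengths, condition, units = "rpkm")
}

# brute-force per-read window counter (independent oracle)
brute_force_counts <- function(windows, readset) {
  mid <- floor((readset$start + readset$end) / 2)
  vapply(seq_len(nrow(windows)), function(i) {
    sum(readset$chrom == windows$chrom[i] &
          mid >= windows$win_start[i] & mid < windows$win_end[i])
  }, numeric(1))
}
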