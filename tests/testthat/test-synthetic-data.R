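test_that("genome simulation handles the empty case and is deterministic", {
  cfg <- small_config()
  empty <- simulate_genome(sim_config(n_genes = 0))
  expect_s3_class(empty, "genome_annotation")
  expect_equal(nrow(empty), 0)

  a1 <- simulate_genome(cfg)
  a2 <- simulate_genome(cfg)
  expect_identical(a1, a2)
  expect_false(identical(a1, simulate_genome(small_config(seed = 2L))))
})

test_that("simulated genes never overlap and keep TSSs away from chromosome ends", {
  cfg <- sim_config(seed = 11)  # 2,000 genes on one 100 Mb chromosome
  ann <- simulate_genome(cfg)
  expect_equal(nrow(ann), 2000)
  expect_equal(anyDuplicated(ann$gene_id), 0)
  # exhaustive pairwise interval overlap scan
  for (chr in unique(ann$chrom)) {
    g <- ann[ann$chrom == chr, ]
    ov <- outer(g$start, g$end, `<`) & outer(g$end, g$start, `>`)
    diag(ov) <- FALSE
    expect_false(any(ov))
  }
  tss <- tss_positions(ann)
  lens <- chrom_sizes(ann)[ann$chrom]
  expect_true(all(tss >= 5000 & tss <= lens - 5000))
  expect_true(all(table(ann$strand) > 0))
})

test_that("genome simulation raises a capacity error when genes cannot fit", {
  cfg <- sim_config(chrom_sizes = c(chr1 = 30000), n_genes = 10, seed = 1)
  expect_error(simulate_genome(cfg), "capacity")
})

test_that("ground truth is internally consistent", {
  cfg <- small_config(seed = 5)
  ann <- simulate_genome(cfg)
  truth <- simulate_ground_truth(ann, cfg)
  expect_true(all(truth$target_genes %in% truth$bound_genes$POLII))
  expect_true(all(truth$target_genes %in% truth$bound_genes$CMYC))
  expect_true(all(truth$target_genes %in% truth$bound_genes$SOX2))
  # targets are exactly the triple intersection
  expect_setequal(truth$target_genes,
                  Reduce(intersect, truth$bound_genes))
  expect_true(all(truth$amplification > 0))
  expect_setequal(names(truth$amplification), truth$target_genes)
})

test_that("ChIP simulation conserves read count and rejects unknown factors", {
  cfg <- small_config(seed = 2)
  ann <- simulate_genome(cfg)
  truth <- simulate_ground_truth(ann, cfg)
  rs <- simulate_chip_reads(ann, truth, cfg, "POLII")
  expect_equal(total_reads(rs), cfg$chip_reads_per_factor)
  expect_true(all(rs$start >= 0))
  expect_true(all(rs$end <= chrom_sizes(ann)[rs$chrom]))
  expect_true(all(rs$end - rs$start == cfg$read_length))
  expect_identical(rs, simulate_chip_reads(ann, truth, cfg, "POLII"))
  # hyphenated alias maps to the same normalized factor
  expect_identical(simulate_chip_reads(ann, truth, cfg, "C-MYC"),
                   simulate_chip_reads(ann, truth, cfg, "CMYC"))
  expect_error(simulate_chip_reads(ann, truth, cfg, "NANOG"), "unknown factor")
})

test_that("with no enrichment, promoter-window read mass matches the uniform expectation", {
  for (case in list(list(chip_enrichment = 0),
                    list(target_fraction = 0, polii_extra_fraction = 0,
                         factor_extra_fraction = 0))) {
    cfg <- do.call(small_config, c(list(seed = 3), case))
    ann <- simulate_genome(cfg)
    truth <- simulate_ground_truth(ann, cfg)
    rs <- simulate_chip_reads(ann, truth, cfg, "SOX2")
    win <- build_tss_windows(ann)
    wing <- GenomicRanges::reduce(GenomicRanges::GRanges(
      win$chrom, IRanges::IRanges(win$win_start + 1, win$win_end)))
    p_exp <- sum(GenomicRanges::width(wing)) / sum(cfg$chrom_sizes)
    mid <- floor((rs$start + rs$end) / 2)
    hits <- GenomicRanges::countOverlaps(
      GenomicRanges::GRanges(rs$chrom, IRanges::IRanges(mid + 1, mid + 1)),
      wing)
    n <- total_reads(rs)
    sd3 <- 3 * sqrt(n * p_exp * (1 - p_exp))
    expect_lt(abs(sum(hits > 0) - n * p_exp), sd3)
  }
})

test_that("bound-component reads concentrate within 3 frag_sd of their TSS", {
  # near-saturating enrichment makes virtually every read a signal read
  cfg <- small_config(seed = 4, chip_enrichment = 1e4, frag_sd = 500)
  ann <- simulate_genome(cfg)
  truth <- simulate_ground_truth(ann, cfg)
  rs <- simulate_chip_reads(ann, truth, cfg, "CMYC")
  tss <- tss_positions(ann)[truth$bound_genes$CMYC]
  mid <- floor((rs$start + rs$end) / 2)
  near <- vapply(mid, function(m) any(abs(m - tss) <= 1500), logical(1))
  expect_gte(mean(near), 0.90)
})

test_that("expression simulation emits integer NB counts with the stated parameterization", {
  cfg <- small_config(seed = 6)
  ann <- simulate_genome(cfg)
  truth <- simulate_ground_truth(ann, cfg)
  em <- simulate_expression(ann, truth, cfg)
  expect_equal(em$units, "counts")
  expect_true(all(em$values >= 0))
  expect_true(all(em$values == floor(em$values)))
  expect_equal(ncol(em$values), sum(cfg$n_replicates))
  expect_identical(em$values,
                   simulate_expression(ann, truth, cfg)$values)
  expect_error(small_config(expr_dispersion = -1), "dispersion")
})

test_that("vanishing dispersion approaches the Poisson mean-variance limit", {
  cfg <- sim_config(chrom_sizes = c(chr1 = 2e7), n_genes = 200, seed = 7,
                    expr_dispersion = 1e-8,
                    n_replicates = c(otosphere = 60, imop = 1))
  ann <- simulate_genome(cfg)
  truth <- simulate_ground_truth(ann, cfg)
  em <- simulate_expression(ann, truth, cfg)
  oto <- em$values[, em$condition == "otosphere"]
  m <- rowMeans(oto)
  v <- apply(oto, 1, var)
  keep <- m > 20  # variance ratio is noisy for tiny means
  expect_gt(sum(keep), 50)
  expect_lt(abs(median(v[keep] / m[keep]) - 1), 0.25)
})

test_that("the amplification factor is recovered from target-gene RPKM ratios", {
  cfg <- sim_config(seed = 8)  # 2,000 genes, factor 1.5, 3 vs 2 replicates
  ann <- simulate_genome(cfg)
  truth <- simulate_ground_truth(ann, cfg)
  em <- simulate_expression(ann, truth, cfg)
  # equal library sizes isolate the generator's multiplicative signal from
  # compositional depth differences
  r <- rpkm(em, library_sizes = rep(1e6, ncol(em$values)))
  fs <- fold_summary(r, truth$target_genes)
  expect_lt(abs(fs$mean_fold - 1.5), 0.15)
  # non-targets stay at fold ~1
  others <- setdiff(ann$gene_id, truth$target_genes)
  fs0 <- fold_summary(r, others)
  expect_lt(abs(fs0$mean_fold - 1), 0.15)
})

test_that("the two conditions are exchangeable when amplification is off", {
  cfg <- sim_config(chrom_sizes = c(chr1 = 2e7), n_genes = 400,
                    amplification_factor = 1, seed = 1)
  ann <- simulate_genome(cfg)
  truth <- simulate_ground_truth(ann, cfg)
  # disjoint gene halves make the two condition samples independent, so the
  # Welch p-value is uniform under exchangeability
  half <- seq_len(200)
  ps <- vapply(seq_len(200), function(s) {
    cfg_s <- sim_config(chrom_sizes = c(chr1 = 2e7), n_genes = 400,
                        amplification_factor = 1, seed = s)
    em <- simulate_expression(ann, truth, cfg_s)
    r <- rpkm(em, library_sizes = rep(1e6, ncol(em$values)))$values
    a <- log10(1 + rowMeans(r[half, em$condition == "otosphere",
                              drop = FALSE]))
    b <- log10(1 + rowMeans(r[-half, em$condition == "imop", drop = FALSE]))
    welch_t(a, b)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("bisulfite clone simulation follows the conversion chemistry", {
  ref <- paste(rep("TACGGA", 20), collapse = "")  # 20 CpG sites
  sites <- find_cpg_sites(ref)
  expect_length(sites, 20)

  # all unmethylated + complete conversion: every CpG cytosine reads T
  r0 <- simulate_bisulfite_clones(ref, rep(0, 20), n_clones = 4,
                                  conversion_rate = 1, seed = 1)
  bases0 <- sapply(r0$clones, function(s)
    substring(s, sites + 1, sites + 1), USE.NAMES = FALSE)
  expect_true(all(bases0 == "T"))

  # all methylated: every CpG cytosine stays C
  r1 <- simulate_bisulfite_clones(ref, rep(1, 20), n_clones = 4,
                                  conversion_rate = 1, seed = 1)
  bases1 <- sapply(r1$clones, function(s)
    substring(s, sites + 1, sites + 1), USE.NAMES = FALSE)
  expect_true(all(bases1 == "C"))

  expect_error(simulate_bisulfite_clones(ref, rep(0.5, 3), 2, 1, 1),
               "CpG sites")
})

test_that("simulated methylation rates match their per-site probabilities", {
  ref <- paste(rep("ATTCGGA", 15), collapse = "")  # 15 CpG sites
  res <- simulate_bisulfite_clones(ref, rep(0.8, 15), n_clones = 10,
                                   conversion_rate = 1, seed = 9)
  n <- length(res$states)
  expect_equal(n, 150)
  sd3 <- 3 * sqrt(n * 0.8 * 0.2)
  expect_lt(abs(sum(res$states) - n * 0.8), sd3)
  expect_identical(res$states,
                   simulate_bisulfite_clones(ref, rep(0.8, 15), 10, 1, 9)$states)
})
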