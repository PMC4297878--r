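test_that("promoter windows are strand-aware and clamped", {
  ann <- toy_annotation()
  win <- build_tss_windows(ann, flank = 5000)
  # + strand gene 10,000-20,000: TSS = start
  expect_equal(win$tss[win$gene_id == "gA"], 10000)
  expect_equal(win$win_start[win$gene_id == "gA"], 5000)
  expect_equal(win$win_end[win$gene_id == "gA"], 15000)
  # - strand gene 40,000-50,000: TSS = end - 1
  expect_equal(win$tss[win$gene_id == "gB"], 49999)
  expect_equal(win$win_start[win$gene_id == "gB"], 44999)
  expect_equal(win$win_end[win$gene_id == "gB"], 54999)
  # clamping at the chromosome start
  ann2 <- genome_annotation("gE", "chr1", 3000, 9000, "+",
                            c(chr1 = 1e6))
  win2 <- build_tss_windows(ann2, flank = 5000)
  expect_equal(win2$win_start, 0)
  expect_equal(win2$win_end, 8000)
  expect_error(build_tss_windows(ann, flank = 0), "flank")
  expect_error(genome_annotation("g", "chrX", 0, 10, "+", c(chr1 = 100)),
               "unknown chromosome")
})

test_that("window counting assigns reads by midpoint with half-open bounds", {
  ann <- toy_annotation()
  win <- build_tss_windows(ann, flank = 5000)
  empty <- read_set(character(), numeric(), numeric(), "POLII")
  expect_equal(unname(count_window_reads(win, empty)), rep(0L, 3))

  # gA window is [5000, 15000): midpoint exactly at win_end must not count
  rs <- read_set(rep("chr1", 3),
                 start = c(14995, 14994, 4995),
                 end = c(15005, 15004, 5005),  # midpoints 15000, 14999, 5000
                 "POLII")
  cnt <- count_window_reads(win, rs)
  expect_equal(unname(cnt["gA"]), 2L)  # 14999 and 5000 in, 15000 out
})

test_that("window counting matches the brute-force per-read oracle", {
  set.seed(101)
  n_win <- 80
  starts <- sort(sample(0:(5e6 - 1e4), n_win))
  ann <- genome_annotation(sprintf("g%03d", 1:n_win), "chr1", starts,
                           starts + 5000,
                           sample(c("+", "-"), n_win, TRUE),
                           c(chr1 = 5e6))
  win <- build_tss_windows(ann, flank = 5000)
  rstart <- sample(0:(5e6 - 50), 2e4, replace = TRUE)
  rs <- read_set(rep("chr1", 2e4), rstart, rstart + 50, "POLII")
  expect_equal(unname(count_window_reads(win, rs)),
               as.integer(brute_force_counts(win, rs)))
})

test_that("binding calls follow the Poisson/BH/fold-enrichment rule", {
  ann <- toy_annotation()
  win <- build_tss_windows(ann, flank = 5000)
  # counts chosen per gene: 0 (unbound, p = 1), strongly enriched, lambda-ish
  rs <- read_set(rep("chr1", 100), seq(0, 990, 10), seq(50, 1040, 10), "SOX2")
  genome_size <- 1e6
  counts <- setNames(c(0L, 50L, 1L), c("gA", "gB", "gC"))
  occ <- call_binding(counts, rs, win, genome_size)
  expect_equal(occ$lambda, rep(100 * 10000 / 1e6, 3))  # = 1
  expect_equal(occ$p[occ$gene_id == "gA"], 1)
  expect_false(occ$bound[occ$gene_id == "gA"])
  expect_true(occ$bound[occ$gene_id == "gB"])
  # count equal to lambda: enrichment 1 < 2 blocks the call regardless of p
  expect_false(occ$bound[occ$gene_id == "gC"])
  expect_true(all(occ$q >= occ$p & occ$q <= 1))
})

test_that("the Poisson upper tail matches direct summation to 1e-12", {
  lambda <- 5; count <- 25
  # direct upper-tail summation (terms beyond k = 170 are below 1e-200)
  direct <- sum(exp(-lambda) * lambda^(count:170) / factorial(count:170))
  ann <- toy_annotation()
  win <- build_tss_windows(ann, flank = 5000)[1, ]
  attr(win, "flank") <- 5000
  rs <- read_set(rep("chr1", 500), seq_len(500), seq_len(500) + 50, "SOX2")
  occ <- call_binding(setNames(25L, "gA"), rs, win, genome_size = 1e6)
  expect_equal(occ$lambda, 5)
  expect_equal(occ$p, direct, tolerance = 1e-12)
})

test_that("BH adjustment is monotone in p", {
  set.seed(5)
  p <- runif(200)^2
  q <- p.adjust(p, "BH")
  expect_true(all(diff(q[order(p)]) >= 0))  # same ordering by p and by q
  expect_true(all(q >= p & q <= 1))
})

test_that("target calling intersects POLII and factor binding", {
  mk <- function(f, bound) data.frame(
    gene_id = c("g1", "g2", "g3"), factor = f, count = 1L, lambda = 1,
    enrichment = 1, p = 0.5, q = 0.5, bound = bound)
  # POLII bound nowhere -> empty target set
  occ <- rbind(mk("POLII", c(FALSE, FALSE, FALSE)),
               mk("SOX2", c(TRUE, TRUE, TRUE)))
  expect_length(call_targets(occ, "SOX2"), 0)
  # factor bound everywhere POLII is -> target set equals POLII-bound set
  occ2 <- rbind(mk("POLII", c(TRUE, TRUE, FALSE)),
                mk("SOX2", c(TRUE, TRUE, TRUE)))
  tg <- call_targets(occ2, "SOX2")
  expect_setequal(as.character(tg), c("g1", "g2"))
  # target set is always contained in both bound sets
  occ3 <- rbind(mk("POLII", c(TRUE, FALSE, TRUE)),
                mk("CMYC", c(FALSE, TRUE, TRUE)))
  tg3 <- call_targets(occ3, "C-MYC")
  expect_true(all(tg3 %in% occ3$gene_id[occ3$factor == "POLII" & occ3$bound]))
  expect_true(all(tg3 %in% occ3$gene_id[occ3$factor == "CMYC" & occ3$bound]))
  expect_error(call_targets(mk("SOX2", rep(TRUE, 3)), "SOX2"), "lacks rows")
})

test_that("false-positive target rate stays below the FDR threshold on null data", {
  fp <- vapply(seq_len(50), function(s) {
    cfg <- sim_config(chrom_sizes = c(chr1 = 5e6), n_genes = 100,
                      chip_reads_per_factor = 5000, seed = s,
                      target_fraction = 0, polii_extra_fraction = 0,
                      factor_extra_fraction = 0)
    ann <- simulate_genome(cfg)
    truth <- simulate_ground_truth(ann, cfg)
    win <- build_tss_windows(ann)
    occ <- do.call(rbind, lapply(c("POLII", "SOX2"), function(f) {
      rs <- simulate_chip_reads(ann, truth, cfg, f)
      call_binding(count_window_reads(win, rs), rs, win, 5e6)
    }))
    length(call_targets(occ, "SOX2")) / nrow(ann)
  }, numeric(1))
  expect_lte(mean(fp), 0.05)
})

test_that("overlap statistics reproduce the printed co-occupancy fractions", {
  # 4,994 SOX2 targets, 5,422 C-MYC targets, 4,231 shared
  sox2 <- sprintf("s%05d", 1:4994)
  cmyc <- c(sox2[1:4231], sprintf("c%05d", 1:(5422 - 4231)))
  ov <- overlap_stats(sox2, cmyc)
  expect_equal(ov$n_a, 4994)
  expect_equal(ov$n_b, 5422)
  expect_equal(ov$n_intersect, 4231)
  expect_equal(round(ov$pct_a_in_b), 85)
  # symmetry of the intersection count
  expect_equal(overlap_stats(cmyc, sox2)$n_intersect, ov$n_intersect)
})

test_that("overlap statistics handle identity, disjointness and empty sets", {
  a <- c("x", "y", "z")
  same <- overlap_stats(a, a)
  expect_equal(same$pct_a_in_b, 100)
  expect_equal(same$pct_b_in_a, 100)
  dis <- overlap_stats(a, c("u", "v"))
  expect_equal(dis$pct_a_in_b, 0)
  empty <- overlap_stats(character(), a)
  expect_true(is.na(empty$pct_a_in_b))
  expect_equal(empty$pct_b_in_a, 0)
})
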