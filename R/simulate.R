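# Run expr under a derived stream seed, restoring the caller's RNG state.
.with_stream_seed <- function(master, stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(master, stream))
  expr
}

#' Simulate a gene annotation
#'
#' Places `n_genes` non-overlapping gene bodies on the configured chromosomes
#' (allocation proportional to usable chromosome length), with strands drawn
#' 50/50 and every TSS at least 5 kb from chromosome ends. Placement uses
#' per-chromosome slots, so non-overlap is guaranteed by construction; a
#' capacity error is raised when the slots cannot hold the longest allowed
#' gene body.
#'
#' @param config a [sim_config()].
#' @return a [genome_annotation()]; deterministic given `config$seed`.
#' @export
simulate_genome <- function(config) {
  margin <- 5000
  if (config$n_genes == 0)
    return(genome_annotation(character(), character(), numeric(), numeric(),
                             character(), config$chrom_sizes))
  .with_stream_seed(config$seed, "genome", {
    usable <- pmax(config$chrom_sizes - 2 * margin, 0)
    n_per <- floor(config$n_genes * usable / sum(usable))
    rem <- config$n_genes - sum(n_per)
    if (rem > 0) {
      o <- order(usable, decreasing = TRUE)
      n_per[o[seq_len(rem)]] <- n_per[o[seq_len(rem)]] + 1L
    }
    len_max <- config$gene_length_range[2]
    rows <- lapply(seq_along(config$chrom_sizes), function(ci) {
      n_c <- n_per[ci]
      if (n_c == 0) return(NULL)
      slot <- floor(usable[ci] / n_c)
      if (slot < len_max)
        stop("capacity error: cannot place ", n_c, " non-overlapping genes on ",
             names(config$chrom_sizes)[ci])
      len <- sample(seq(config$gene_length_range[1], len_max), n_c,
                    replace = TRUE)
      offset <- floor(runif(n_c) * (slot - len + 1))
      start <- margin + (seq_len(n_c) - 1) * slot + offset
      data.frame(chrom = names(config$chrom_sizes)[ci], start = start,
                 end = start + len,
                 strand = sample(c("+", "-"), n_c, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    ids <- sprintf("gene%05d", seq_len(nrow(df)))
    genome_annotation(ids, df$chrom, df$start, df$end, df$strand,
                      config$chrom_sizes)
  })
}

#' Simulate binding ground truth
#'
#' Draws the true co-occupancy target set (`target_fraction` of genes, bound
#' by POLII and both factors) plus disjoint factor-specific extras, so that
#' the POLII/CMYC/SOX2 bound sets are strict supersets of the target set and
#' the targets are exactly the genes bound by all three. Target genes carry
#' the configured amplification multiplier.
#'
#' @param annotation a [genome_annotation()].
#' @param config a [sim_config()].
#' @return a `ground_truth` list with `bound_genes` (named list of gene-id
#'   vectors for POLII/CMYC/SOX2), `target_genes`, and `amplification`
#'   (named multipliers).
#' @export
simulate_ground_truth <- function(annotation, config) {
  .with_stream_seed(config$seed, "truth", {
    ids <- annotation$gene_id
    n <- length(ids)
    n_t <- round(config$target_fraction * n)
    n_p <- round(config$polii_extra_fraction * n)
    n_f <- round(config$factor_extra_fraction * n)
    pool <- sample(ids)
    targets <- sort(pool[seq_len(n_t)])
    rest <- pool[-seq_len(n_t)]
    polii_extra <- rest[seq_len(n_p)]
    cmyc_extra <- rest[n_p + seq_len(n_f)]
    sox2_extra <- rest[n_p + n_f + seq_len(n_f)]
    truth <- list(
      bound_genes = list(POLII = sort(c(targets, polii_extra)),
                         CMYC = sort(c(targets, cmyc_extra)),
                         SOX2 = sort(c(targets, sox2_extra))),
      target_genes = targets,
      amplification = setNames(rep(config$amplification_factor,
                                   length(targets)), targets))
    class(truth) <- "ground_truth"
    truth
  })
}

.normalize_factor <- function(factor_name) {
  f <- toupper(gsub("-", "", factor_name))
  if (!f %in% c("POLII", "CMYC", "SOX2"))
    stop("unknown factor: ", factor_name, " (expected POLII, C-MYC or SOX2)")
  f
}

#' Simulate ChIP reads for one factor
#'
#' Mixture model: each read is, with probability `S / (G + S)`, a signal read
#' whose center is `TSS + Normal(0, frag_sd)` for a uniformly chosen bound
#' gene; otherwise its center is uniform over the genome. `G` is the genome
#' length and `S = n_bound * (chip_enrichment - 1) * 2 * flank`, which makes
#' the realized read density in a bound ±`flank` promoter window approximately
#' `chip_enrichment`-fold the background density. `chip_enrichment <= 1` (or
#' no bound genes) yields pure background. Reads are fixed-length single-end
#' intervals clipped to chromosome bounds; exactly
#' `config$chip_reads_per_factor` are emitted.
#'
#' @param annotation a [genome_annotation()].
#' @param ground_truth a `ground_truth` from [simulate_ground_truth()].
#' @param config a [sim_config()].
#' @param factor_name `"POLII"`, `"C-MYC"`/`"CMYC"` or `"SOX2"`.
#' @return a [read_set()]; deterministic given `config$seed` and the factor.
#' @export
simulate_chip_reads <- function(annotation, ground_truth, config, factor_name) {
  f <- .normalize_factor(factor_name)
  bound <- intersect(ground_truth$bound_genes[[f]], annotation$gene_id)
  sizes <- config$chrom_sizes
  G <- sum(sizes)
  S <- length(bound) * max(config$chip_enrichment - 1, 0) * 2 * config$flank
  p_signal <- S / (G + S)
  rl <- config$read_length
  .with_stream_seed(config$seed, paste0("chip_", f), {
    n <- config$chip_reads_per_factor
    n_sig <- rbinom(1, n, p_signal)
    tsspos <- tss_positions(annotation)
    out <- vector("list", 2)
    if (n_sig > 0) {
      gi <- sample(bound, n_sig, replace = TRUE)
      center <- round(tsspos[gi] + rnorm(n_sig, 0, config$frag_sd))
      chrom <- annotation$chrom[match(gi, annotation$gene_id)]
      start <- pmin(pmax(center - floor(rl / 2), 0), sizes[chrom] - rl)
      out[[1]] <- data.frame(chrom = chrom, start = start)
    }
    n_bg <- n - n_sig
    if (n_bg > 0) {
      chrom <- sample(names(sizes), n_bg, replace = TRUE,
                      prob = sizes / sum(sizes))
      start <- floor(runif(n_bg) * (sizes[chrom] - rl))
      out[[2]] <- data.frame(chrom = chrom, start = start)
    }
    df <- do.call(rbind, out)
    df <- df[order(df$chrom, df$start), , drop = FALSE]  # coordinate-sorted
    read_set(df$chrom, df$start, df$start + rl, f, sizes)
  })
}

#' Simulate an RNA-seq count experiment
#'
#' Per-gene baseline means are lognormal (`2^Normal(expr_mean_log2,
#' expr_sd_log2)`); counts are negative binomial with variance
#' `mean + dispersion * mean^2`. In the iMOP-like condition, target-gene means
#' are multiplied by their ground-truth amplification factor. An optional
#' ESC-like condition draws an independent baseline (a transcriptome-wide
#' distinct expression program) for clustering checks.
#'
#' @param annotation a [genome_annotation()] supplying gene ids and lengths.
#' @param ground_truth a `ground_truth`.
#' @param config a [sim_config()].
#' @param n_esc number of ESC-like replicates to append (default 0).
#' @return an [expression_matrix()] in counts units whose samples are labeled
#'   by condition (`otosphere`, `imop`, and optionally `esc`); deterministic
#'   given `config$seed`.
#' @export
simulate_expression <- function(annotation, ground_truth, config, n_esc = 0) {
  if (config$expr_dispersion <= 0) stop("expr_dispersion must be positive")
  .with_stream_seed(config$seed, "expression", {
    n <- nrow(annotation)
    ids <- annotation$gene_id
    base <- 2^rnorm(n, config$expr_mean_log2, config$expr_sd_log2)
    amp <- rep(1, n)
    hit <- match(names(ground_truth$amplification), ids)
    amp[hit[!is.na(hit)]] <- ground_truth$amplification[!is.na(hit)]
    size <- 1 / config$expr_dispersion
    n_oto <- config$n_replicates[["otosphere"]]
    n_imop <- config$n_replicates[["imop"]]
    draw <- function(mu, k) {
      matrix(rnbinom(n * k, mu = rep(mu, k), size = size), nrow = n)
    }
    counts <- cbind(draw(base, n_oto), draw(base * amp, n_imop))
    cond <- c(rep("otosphere", n_oto), rep("imop", n_imop))
    if (n_esc > 0) {
      esc_base <- 2^rnorm(n, config$expr_mean_log2, config$expr_sd_log2)
      counts <- cbind(counts, draw(esc_base, n_esc))
      cond <- c(cond, rep("esc", n_esc))
    }
    colnames(counts) <- paste0(cond, "_", sequence(table(cond)[unique(cond)]))
    rownames(counts) <- ids
    expression_matrix(counts, gene_lengths = annotation$end - annotation$start,
                      condition = cond, units = "counts")
  })
}

#' Simulate bisulfite-converted clone sequences
#'
#' For each clone and CpG site, the cytosine is methylated with the site's
#' probability; methylated CpG cytosines are protected and read as C, while
#' unmethylated CpG cytosines and all non-CpG cytosines are converted C -> T
#' with probability `conversion_rate`.
#'
#' @param reference_seq reference sequence (character string over ACGTN).
#' @param site_meth_probs one methylation probability per CpG site in the
#'   reference (ascending site order).
#' @param n_clones number of clones to simulate.
#' @param conversion_rate bisulfite conversion efficiency in (0, 1].
#' @param seed integer seed.
#' @return list with `clones` (character vector of sequences), `states`
#'   (logical clones x sites matrix of true methylation), and `sites`
#'   (0-based CpG offsets).
#' @export
simulate_bisulfite_clones <- function(reference_seq, site_meth_probs, n_clones,
                                      conversion_rate = 1, seed = 1L) {
  sites <- find_cpg_sites(reference_seq)
  if (length(site_meth_probs) != length(sites))
    stop("site_meth_probs has length ", length(site_meth_probs),
         " but the reference has ", length(sites), " CpG sites")
  stopifnot(conversion_rate > 0, conversion_rate <= 1)
  .with_stream_seed(seed, "bisulfite", {
    ref <- strsplit(toupper(reference_seq), "")[[1]]
    c_pos <- which(ref == "C")
    states <- matrix(FALSE, n_clones, length(sites),
                     dimnames = list(sprintf("clone%02d", seq_len(n_clones)),
                                     sites))
    clones <- character(n_clones)
    for (i in seq_len(n_clones)) {
      meth <- runif(length(sites)) < site_meth_probs
      states[i, ] <- meth
      s <- ref
      protected <- (sites + 1)[meth]
      convertible <- setdiff(c_pos, protected)
      converted <- convertible[runif(length(convertible)) < conversion_rate]
      s[converted] <- "T"
      clones[i] <- paste(s, collapse = "")
    }
    list(clones = clones, states = states, sites = sites)
  })
}

#' Simulate a cumulative growth series
#'
#' Exponential growth sampled at the given timepoints with multiplicative
#' lognormal noise, emulating weekly cumulative cell counts of a continuously
#' passaged culture.
#'
#' @param doubling_hr true doubling time in hours.
#' @param timepoints_hr sampling times in hours.
#' @param n0 starting cell count.
#' @param noise_sd SD of multiplicative (log) noise; 0.05 is 5% noise.
#' @param seed integer seed.
#' @return a data frame with `time_hr` and `count`.
#' @export
simulate_growth_series <- function(doubling_hr, timepoints_hr, n0 = 1e4,
                                   noise_sd = 0.05, seed = 1L) {
  stopifnot(doubling_hr > 0, length(timepoints_hr) >= 2)
  .with_stream_seed(seed, "growth", {
    mu <- n0 * 2^(timepoints_hr / doubling_hr)
    count <- mu * exp(rnorm(length(mu), 0, noise_sd))
    data.frame(time_hr = timepoints_hr, count = count)
  })
}
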