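#' Write / read a target-set gene list
#' @param targets character vector of gene ids.
#' @param path file path (one id per line).
#' @export
write_targets <- function(targets, path) {
  writeLines(as.character(targets), path)
  invisible(path)
}

#' @rdname write_targets
#' @export
read_targets <- function(path) readLines(path)

#' Run the full synthetic-to-report pipeline
#'
#' Executes the stages in order: simulate genome + ground truth, simulate ChIP
#' reads for POLII/C-MYC/SOX2, build ±flank promoter windows, count and call
#' binding, derive the SOX2 and C-MYC POLII-anchored target sets and their
#' overlap, simulate expression, compute the fold summary and the
#' CDF shift test on the co-occupied targets, and the sample Spearman /
#' clustering comparison. All stage outputs are written under `out_dir` and
#' the headline numbers are returned (and written) as a JSON-able report.
#' Deterministic for a fixed config.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @param flank,q_threshold,min_enrichment binding-call parameters.
#' @param verbose log stage progress to stderr.
#' @return the report list, invisibly if `out_dir` is set.
#' @export
run_full <- function(config, out_dir = NULL, flank = config$flank,
                     q_threshold = 0.05, min_enrichment = 2.0,
                     verbose = FALSE) {
  say <- function(...) if (verbose) message("[ampscan] ", ...)
  t0 <- Sys.time()
  say("simulating genome and ground truth")
  ann <- simulate_genome(config)
  truth <- simulate_ground_truth(ann, config)
  genome_size <- sum(config$chrom_sizes)
  say("simulating ChIP reads and calling binding")
  windows <- build_tss_windows(ann, flank = flank)
  occ <- list(); reads <- list()
  for (f in c("POLII", "CMYC", "SOX2")) {
    reads[[f]] <- simulate_chip_reads(ann, truth, config, f)
    cnt <- count_window_reads(windows, reads[[f]])
    occ[[f]] <- call_binding(cnt, reads[[f]], windows, genome_size,
                             q_threshold, min_enrichment)
  }
  occupancy <- do.call(rbind, occ)
  sox2_targets <- call_targets(occupancy, "SOX2")
  cmyc_targets <- call_targets(occupancy, "CMYC")
  ov <- overlap_stats(sox2_targets, cmyc_targets)
  co_targets <- intersect(sox2_targets, cmyc_targets)
  say("simulating expression and testing amplification")
  em <- simulate_expression(ann, truth, config)
  amp <- if (length(co_targets) >= 2) {
    fs <- fold_summary(em, co_targets)
    sh <- cdf_shift_test(em, co_targets)
    list(max_fold = fs$max_fold, mean_fold = fs$mean_fold,
         median_fold = fs$median_fold, n_undefined = fs$n_undefined,
         t = sh$t, df = sh$df, p = sh$p)
  } else NULL
  rho <- spearman_matrix(rpkm(em))
  dend <- hierarchical_cluster(rho)
  report <- list(
    seed = config$seed, n_genes = config$n_genes,
    n_true_targets = length(truth$target_genes),
    n_sox2_targets = length(sox2_targets),
    n_cmyc_targets = length(cmyc_targets),
    n_overlap = ov$n_intersect,
    pct_sox2_in_cmyc = ov$pct_a_in_b,
    amplification = amp,
    min_spearman_rho = min(rho),
    dendrogram = dend$newick,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    say("writing outputs to ", out_dir)
    write_bed6(ann, file.path(out_dir, "annotation.bed"))
    for (f in names(reads))
      write_bed3(reads[[f]], file.path(out_dir, paste0("reads_", f, ".bed")))
    write.table(occupancy, file.path(out_dir, "occupancy.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_targets(sox2_targets, file.path(out_dir, "targets_SOX2.txt"))
    write_targets(cmyc_targets, file.path(out_dir, "targets_CMYC.txt"))
    write_counts(em, file.path(out_dir, "counts.tsv"))
    report_out <- report
    report_out$elapsed_sec <- NULL  # keep report byte-identical across runs
    jsonlite::write_json(report_out, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}

#' Validate pipeline input files
#'
#' Checks BED interval sanity (start < end, within chromosome bounds,
#' sortedness within chromosome), count-matrix integrality and
#' non-negativity, and FASTA alphabet. Never mutates inputs.
#'
#' @param annotation_bed,reads_bed,counts_tsv,fasta optional file paths;
#'   `reads_bed` may be a vector.
#' @param chrom_sizes named chromosome lengths used for bounds checks.
#' @return a diagnostics data frame (`file`, `line`, `message`); zero rows
#'   means all supplied inputs are well-formed.
#' @export
validate_inputs <- function(annotation_bed = NULL, reads_bed = NULL,
                            counts_tsv = NULL, fasta = NULL,
                            chrom_sizes = NULL) {
  diags <- list()
  note <- function(file, line, msg)
    diags[[length(diags) + 1]] <<- data.frame(file = file, line = line,
                                              message = msg,
                                              stringsAsFactors = FALSE)
  check_bed <- function(path, n_min_cols) {
    lines <- readLines(path)
    prev <- list()
    for (i in seq_along(lines)) {
      f <- strsplit(lines[i], "\t")[[1]]
      if (length(f) < n_min_cols) {
        note(path, i, sprintf("expected >= %d columns, found %d",
                              n_min_cols, length(f)))
        next
      }
      s <- suppressWarnings(as.numeric(f[2]))
      e <- suppressWarnings(as.numeric(f[3]))
      if (is.na(s) || is.na(e)) { note(path, i, "non-numeric coordinates"); next }
      if (s >= e) note(path, i, sprintf("start >= end (%s >= %s)", f[2], f[3]))
      if (!is.null(chrom_sizes)) {
        if (!f[1] %in% names(chrom_sizes))
          note(path, i, paste("unknown chromosome", f[1]))
        else if (e > chrom_sizes[[f[1]]])
          note(path, i, "interval exceeds chromosome length")
      }
      if (!is.null(prev[[f[1]]]) && s < prev[[f[1]]])
        note(path, i, "intervals not sorted by start within chromosome")
      prev[[f[1]]] <- s
    }
  }
  if (!is.null(annotation_bed)) check_bed(annotation_bed, 6)
  for (rb in reads_bed) check_bed(rb, 3)
  if (!is.null(counts_tsv)) {
    df <- tryCatch(read.table(counts_tsv, sep = "\t", header = TRUE,
                              comment.char = "#", check.names = FALSE,
                              stringsAsFactors = FALSE),
                   error = function(e) e)
    if (inherits(df, "error")) {
      note(counts_tsv, NA_integer_, conditionMessage(df))
    } else {
      vals <- as.matrix(df[, -(1:2), drop = FALSE])
      bad <- which(!is.finite(vals) | vals < 0 | vals != floor(vals),
                   arr.ind = TRUE)
      for (r in seq_len(min(nrow(bad), 20)))
        note(counts_tsv, NA_integer_,
             sprintf("non-integer or negative count for gene %s, sample %s",
                     df[[1]][bad[r, 1]], colnames(vals)[bad[r, 2]]))
      if (any(df[[2]] <= 0))
        note(counts_tsv, NA_integer_, "non-positive gene length")
    }
  }
  if (!is.null(fasta)) {
    seqs <- tryCatch(Biostrings::readDNAStringSet(fasta),
                     error = function(e) e)
    if (inherits(seqs, "error"))
      note(fasta, NA_integer_, conditionMessage(seqs))
    else {
      freq <- Biostrings::alphabetFrequency(seqs)
      extra <- rowSums(freq[, !colnames(freq) %in% c("A", "C", "G", "T", "N"),
                            drop = FALSE])
      for (i in which(extra > 0))
        note(fasta, NA_integer_,
             paste("record", names(seqs)[i], "contains non-ACGTN characters"))
    }
  }
  if (length(diags) == 0)
    return(data.frame(file = character(), line = integer(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, diags)
}
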