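#' Build promoter windows around TSSs
#'
#' One fixed-flank window per gene, `[TSS - flank, TSS + flank)` in 0-based
#' half-open coordinates, clamped to the chromosome. The TSS is strand-aware:
#' `start` for `+` genes, `end - 1` for `-` genes.
#'
#' @param annotation a [genome_annotation()].
#' @param flank half-width in bp (default 5000, i.e. the ±5 kb promoter
#'   region).
#' @return a `promoter_windows` data frame with columns `gene_id`, `chrom`,
#'   `win_start`, `win_end`, `tss`, `strand`; the nominal (unclamped) window
#'   length `2 * flank` is kept in the `flank` attribute so background rates
#'   are not deflated at chromosome edges.
#' @export
build_tss_windows <- function(annotation, flank = 5000) {
  if (flank <= 0) stop("flank must be positive")
  tss <- ifelse(annotation$strand == "+", annotation$start, annotation$end - 1)
  lens <- chrom_sizes(annotation)[annotation$chrom]
  win <- data.frame(gene_id = annotation$gene_id, chrom = annotation$chrom,
                    win_start = pmax(tss - flank, 0),
                    win_end = pmin(tss + flank, lens),
                    tss = tss, strand = annotation$strand,
                    stringsAsFactors = FALSE)
  rownames(win) <- NULL
  attr(win, "flank") <- flank
  attr(win, "chrom_sizes") <- chrom_sizes(annotation)
  class(win) <- c("promoter_windows", "data.frame")
  win
}

#' @export
`[.promoter_windows` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "flank") <- attr(x, "flank")
    attr(out, "chrom_sizes") <- attr(x, "chrom_sizes")
    class(out) <- class(x)
  }
  out
}

#' Count reads per promoter window
#'
#' A read is assigned to a window iff its midpoint (`floor((start + end) / 2)`)
#' lies in `[win_start, win_end)`; a read may count toward several overlapping
#' windows.
#'
#' @param windows a `promoter_windows` from [build_tss_windows()].
#' @param readset a [read_set()].
#' @return integer vector of counts, named by gene id.
#' @export
count_window_reads <- function(windows, readset) {
  counts <- integer(nrow(windows))
  if (nrow(readset) > 0 && nrow(windows) > 0) {
    mid <- floor((readset$start + readset$end) / 2)
    mids <- .as_granges(readset$chrom, mid, mid + 1)
    wins <- .as_granges(windows$chrom, windows$win_start, windows$win_end)
    counts <- GenomicRanges::countOverlaps(wins, mids)
  }
  setNames(as.integer(counts), windows$gene_id)
}

#' Call per-gene factor binding by Poisson enrichment
#'
#' Tests each promoter window's read count against a uniform-background
#' expectation `lambda = total_reads * window_length / genome_size` with a
#' one-sided Poisson upper-tail test `P(X >= count)`, adjusts across genes by
#' Benjamini-Hochberg, and calls a gene bound when `q < q_threshold` and the
#' fold enrichment `count / lambda` is at least `min_enrichment`. Windows
#' clamped at chromosome edges keep their nominal `2 * flank` length in
#' `lambda` so edge genes are not spuriously enriched.
#'
#' @param counts named counts from [count_window_reads()].
#' @param readset the [read_set()] the counts came from (for `total_reads` and
#'   the factor label).
#' @param windows the `promoter_windows` used.
#' @param genome_size total genome length in bp.
#' @param q_threshold BH-FDR threshold (default 0.05).
#' @param min_enrichment minimum fold enrichment over background (default 2).
#' @return an `occupancy_table` data frame: `gene_id`, `factor`, `count`,
#'   `lambda`, `enrichment`, `p`, `q`, `bound`.
#' @export
call_binding <- function(counts, readset, windows, genome_size,
                         q_threshold = 0.05, min_enrichment = 2.0) {
  if (genome_size <= 0) stop("genome_size must be positive")
  n_total <- total_reads(readset)
  if (n_total <= 0) stop("readset has no reads")
  win_len <- rep(2 * attr(windows, "flank"), nrow(windows))
  if (any(win_len <= 0)) stop("zero-length window")
  lambda <- n_total * win_len / genome_size
  cnt <- as.numeric(counts[windows$gene_id])
  p <- ppois(cnt - 1, lambda, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  enr <- cnt / lambda
  out <- data.frame(gene_id = windows$gene_id,
                    factor = factor_name(readset),
                    count = as.integer(cnt), lambda = lambda,
                    enrichment = enr, p = p, q = q,
                    bound = q < q_threshold & enr >= min_enrichment,
                    stringsAsFactors = FALSE)
  class(out) <- c("occupancy_table", "data.frame")
  out
}

#' Derive the POLII-anchored target set of a factor
#'
#' A gene is a target of a transcription factor when both RNA POLII and the
#' factor are bound in its promoter window.
#'
#' @param occupancy an `occupancy_table` (or an rbind of several) containing
#'   rows for `POLII` and for `factor_name`.
#' @param factor_name the transcription factor, e.g. `"SOX2"` or `"C-MYC"`.
#' @return a `target_set`: a character vector of gene ids with the factor name
#'   in the `factor_name` attribute.
#' @export
call_targets <- function(occupancy, factor_name) {
  f <- .normalize_factor(factor_name)
  present <- unique(occupancy$factor)
  if (!all(c("POLII", f) %in% present))
    stop("occupancy table lacks rows for: ",
         paste(setdiff(c("POLII", f), present), collapse = ", "))
  polii <- occupancy$gene_id[occupancy$factor == "POLII" & occupancy$bound]
  tf <- occupancy$gene_id[occupancy$factor == f & occupancy$bound]
  out <- sort(intersect(polii, tf))
  attr(out, "factor_name") <- f
  class(out) <- c("target_set", class(out))
  out
}

#' Overlap statistics of two gene sets
#'
#' @param set_a,set_b character vectors of gene ids.
#' @return list with `n_a`, `n_b`, `n_intersect`, `pct_a_in_b`, `pct_b_in_a`
#'   (percentages; `NA` when the respective set is empty, never 0).
#' @export
overlap_stats <- function(set_a, set_b) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  ni <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_intersect = ni,
       pct_a_in_b = if (length(a) == 0) NA_real_ else 100 * ni / length(a),
       pct_b_in_a = if (length(b) == 0) NA_real_ else 100 * ni / length(b))
}
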