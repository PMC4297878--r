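#' Quantile-normalize the columns of a matrix
#'
#' Classic quantile normalization: each column's rank-r value is replaced by
#' the mean of the r-th order statistics across columns, so every column ends
#' with the same distribution. Tied values within a column receive the mean of
#' the replacement values over their rank range. A single-column matrix is
#' returned unchanged.
#'
#' @param mat numeric matrix, columns = samples/factors.
#' @return matrix of the same shape.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) <= 1) return(mat)
  ref <- rowMeans(apply(mat, 2, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    v <- ref[rank(x, ties.method = "first")]
    out[, j] <- ave(v, match(x, x))
  }
  out
}

#' TSS metaprofile of ChIP read density
#'
#' Bins read midpoints by their strand-oriented offset from the TSS (positive
#' offsets are downstream on the gene's strand; minus-strand windows are
#' mirrored) and averages across windows. A read overlapping several windows
#' contributes to each.
#'
#' @param readset a [read_set()].
#' @param windows a `promoter_windows` from [build_tss_windows()];
#'   `bin_size` must divide `2 * flank`.
#' @param bin_size bin width in bp (default 100).
#' @return a `meta_profile` data frame with `offset` (bin start, bp relative
#'   to the TSS) and `density` (mean reads per window per bin).
#' @export
tss_metaprofile <- function(readset, windows, bin_size = 100) {
  flank <- attr(windows, "flank")
  if ((2 * flank) %% bin_size != 0) stop("bin_size must divide 2 * flank")
  n_bins <- 2L * flank / bin_size
  offsets <- seq(-flank, flank - bin_size, by = bin_size)
  tot <- numeric(n_bins)
  if (nrow(readset) > 0 && nrow(windows) > 0) {
    mid <- floor((readset$start + readset$end) / 2)
    mids <- .as_granges(readset$chrom, mid, mid + 1)
    wins <- .as_granges(windows$chrom, windows$win_start, windows$win_end)
    hits <- GenomicRanges::findOverlaps(wins, mids)
    wi <- S4Vectors::queryHits(hits)
    ri <- S4Vectors::subjectHits(hits)
    raw <- mid[ri] - windows$tss[wi]
    # minus-strand mirroring at the half-open level: offset -> -offset - 1
    ori <- ifelse(windows$strand[wi] == "+", raw, -raw - 1)
    bin <- floor((ori + flank) / bin_size) + 1
    keep <- bin >= 1 & bin <= n_bins
    tab <- tabulate(bin[keep], nbins = n_bins)
    tot <- tab
  }
  out <- data.frame(offset = offsets,
                    density = tot / max(nrow(windows), 1))
  class(out) <- c("meta_profile", "data.frame")
  out
}

#' Combine metaprofiles of several factors, optionally quantile-normalized
#'
#' @param profiles named list of `meta_profile` objects on identical bins.
#' @param quantile logical; quantile-normalize the per-factor density columns
#'   across factors before returning (the usual display normalization for
#'   comparing factors on one axis).
#' @return data frame with `offset` and one density column per factor.
#' @export
metaprofile_matrix <- function(profiles, quantile = TRUE) {
  stopifnot(length(profiles) >= 1)
  off <- profiles[[1]]$offset
  dens <- sapply(profiles, function(p) {
    stopifnot(identical(p$offset, off))
    p$density
  })
  dens <- as.matrix(dens)
  if (quantile) dens <- quantile_normalize(dens)
  cbind(data.frame(offset = off), as.data.frame(dens))
}
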