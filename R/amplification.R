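#' Welch's two-sample t-test
#'
#' The unequal-variance two-sample t statistic
#' `t = (mean(x) - mean(y)) / sqrt(var(x)/nx + var(y)/ny)` with
#' Welch-Satterthwaite degrees of freedom and a two-tailed p-value.
#'
#' @param x,y numeric vectors with at least 2 values each.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("welch_t needs >= 2 values per group")
  vx <- var(x) / nx
  vy <- var(y) / ny
  se2 <- vx + vy
  if (se2 == 0) return(list(t = 0, df = nx + ny - 2, p = 1))
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Per-gene fold-increase summary over a target set
#'
#' For each target gene, fold = (mean RPKM in condition B + pseudocount) /
#' (mean RPKM in condition A + pseudocount). Genes with a zero denominator are
#' reported as undefined and excluded from the max/mean/median with a count.
#'
#' @param em an [expression_matrix()]; counts are converted to RPKM.
#' @param target_genes character vector of gene ids to summarize.
#' @param cond_a baseline condition label (e.g. `"otosphere"`).
#' @param cond_b comparison condition label (e.g. `"imop"`).
#' @param pseudocount added to both means (default 0).
#' @return list with `folds` (named, `NA` where undefined), `max_fold`,
#'   `mean_fold`, `median_fold`, `n_undefined`.
#' @export
fold_summary <- function(em, target_genes, cond_a = "otosphere",
                         cond_b = "imop", pseudocount = 0) {
  if (length(target_genes) == 0) stop("no target genes supplied")
  r <- rpkm(em)
  r <- subset_genes(r, target_genes)
  ia <- r$condition == cond_a
  ib <- r$condition == cond_b
  if (!any(ia) || !any(ib))
    stop("both conditions need at least one sample")
  ma <- rowMeans(r$values[, ia, drop = FALSE]) + pseudocount
  mb <- rowMeans(r$values[, ib, drop = FALSE]) + pseudocount
  folds <- ifelse(ma == 0, NA_real_, mb / ma)
  ok <- folds[!is.na(folds)]
  list(folds = folds, max_fold = max(ok), mean_fold = mean(ok),
       median_fold = median(ok), n_undefined = sum(is.na(folds)))
}

#' Cumulative-distribution shift test for transcriptional amplification
#'
#' Averages RPKM across replicates per condition, keeps genes whose
#' condition-mean RPKM lies within `rpkm_range` (applied per condition, so a
#' gene may enter only one condition's distribution), and tests whether the
#' log10 RPKM distribution of condition B is shifted relative to condition A
#' with Welch's two-tailed t-test. Also returns the two empirical CDFs for
#' plotting.
#'
#' @param em an [expression_matrix()]; counts are converted to RPKM.
#' @param target_genes gene ids the comparison is restricted to.
#' @param cond_a,cond_b condition labels; positive `t` means B is shifted to
#'   the right of (above) A.
#' @param rpkm_range inclusive RPKM filter, default `c(1, 1e4)`.
#' @return list with `t`, `df`, `p`, `n_a`, `n_b`, and `cdf` (data frame of
#'   `condition`, `log10_rpkm`, `cum_fraction`).
#' @export
cdf_shift_test <- function(em, target_genes, cond_a = "otosphere",
                           cond_b = "imop", rpkm_range = c(1, 1e4)) {
  r <- rpkm(em)
  r <- subset_genes(r, target_genes)
  ma <- rowMeans(r$values[, r$condition == cond_a, drop = FALSE])
  mb <- rowMeans(r$values[, r$condition == cond_b, drop = FALSE])
  xa <- log10(ma[ma >= rpkm_range[1] & ma <= rpkm_range[2]])
  xb <- log10(mb[mb >= rpkm_range[1] & mb <= rpkm_range[2]])
  if (length(xa) < 2 || length(xb) < 2)
    stop("fewer than 2 genes pass the RPKM filter in a condition")
  w <- welch_t(xb, xa)
  cdf <- rbind(
    data.frame(condition = cond_a, log10_rpkm = sort(xa),
               cum_fraction = seq_along(xa) / length(xa)),
    data.frame(condition = cond_b, log10_rpkm = sort(xb),
               cum_fraction = seq_along(xb) / length(xb)))
  list(t = w$t, df = w$df, p = w$p, n_a = length(xa), n_b = length(xb),
       cdf = cdf)
}
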