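#' Spearman correlation matrix of samples
#'
#' Rank correlation between every pair of samples, with average-rank tie
#' handling. A sample with constant values has undefined correlations: its
#' off-diagonal entries are `NA` (an explicit undefined marker), the diagonal
#' stays 1.
#'
#' @param em an [expression_matrix()] or a plain genes x samples matrix.
#' @return symmetric matrix of Spearman's rho with unit diagonal.
#' @export
spearman_matrix <- function(em) {
  mat <- if (inherits(em, "expression_matrix")) em$values else as.matrix(em)
  stopifnot(ncol(mat) >= 2, nrow(mat) >= 3)
  rho <- suppressWarnings(cor(mat, method = "spearman"))
  diag(rho) <- 1
  rho
}

#' Average-linkage hierarchical clustering of samples
#'
#' Agglomerates samples on the distance `d = 1 - rho` with average linkage.
#' Samples are ordered lexicographically by name before clustering so that
#' tie-breaking is deterministic.
#'
#' @param corr symmetric correlation matrix with sample names.
#' @return an `amp_dendrogram` list: `merge`, `height`, `order`, `labels`
#'   (the [stats::hclust()] encoding), `newick` (Newick string with branch
#'   lengths), and `hclust` (the underlying object).
#' @export
hierarchical_cluster <- function(corr) {
  corr <- as.matrix(corr)
  if (!isSymmetric(unname(corr), tol = 1e-12)) stop("correlation matrix must be symmetric")
  if (is.null(rownames(corr))) stop("correlation matrix needs sample names")
  o <- order(rownames(corr))
  d <- as.dist(1 - corr[o, o])
  hc <- hclust(d, method = "average")
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, newick = newick, hclust = hc),
            class = "amp_dendrogram")
}

#' Pairwise differential expression between two conditions
#'
#' Converts counts to RPKM, then per gene computes
#' `log2((mean RPKM_B + pc) / (mean RPKM_A + pc))` and Welch's t-test on
#' `log2(RPKM + pc)` across replicates, with BH adjustment across genes. With
#' a single replicate in either group only fold changes are emitted.
#'
#' @param em an [expression_matrix()] containing both conditions.
#' @param cond_a,cond_b condition labels (fold changes are B over A).
#' @param pseudocount stabilizing pseudocount (default 1).
#' @return data frame: `gene_id`, `log2_fc`, `t`, `p`, `q`.
#' @export
differential_expression <- function(em, cond_a = "otosphere",
                                    cond_b = "imop", pseudocount = 1) {
  r <- rpkm(em)
  ia <- which(r$condition == cond_a)
  ib <- which(r$condition == cond_b)
  if (length(ia) == 0 || length(ib) == 0)
    stop("both conditions must be present")
  la <- log2(r$values[, ia, drop = FALSE] + pseudocount)
  lb <- log2(r$values[, ib, drop = FALSE] + pseudocount)
  lfc <- log2((rowMeans(r$values[, ib, drop = FALSE]) + pseudocount) /
                (rowMeans(r$values[, ia, drop = FALSE]) + pseudocount))
  if (length(ia) >= 2 && length(ib) >= 2) {
    tests <- lapply(seq_len(nrow(la)), function(i) welch_t(lb[i, ], la[i, ]))
    tval <- vapply(tests, `[[`, numeric(1), "t")
    p <- vapply(tests, `[[`, numeric(1), "p")
    q <- p.adjust(p, "BH")
  } else {
    tval <- p <- q <- rep(NA_real_, nrow(la))
  }
  data.frame(gene_id = rownames(r$values), log2_fc = lfc, t = tval,
             p = p, q = q, stringsAsFactors = FALSE)
}

#' Hypergeometric gene-set enrichment
#'
#' For each term, the upper-tail probability of drawing at least the observed
#' number of term genes in a query of size n from a universe of size N
#' containing K term genes, BH-adjusted across terms.
#'
#' @param query_genes character vector (must be a subset of `universe`).
#' @param universe character vector of all considered genes.
#' @param term_map data frame with columns `gene` and `term` (gene-to-term
#'   assignments, e.g. a GO-slim annotation supplied by the user).
#' @return data frame: `term`, `term_size`, `overlap`, `p`, `q`, sorted by p.
#' @export
gene_set_enrichment <- function(query_genes, universe, term_map) {
  query <- unique(as.character(query_genes))
  universe <- unique(as.character(universe))
  missing <- setdiff(query, universe)
  if (length(missing) > 0)
    stop("query genes absent from universe: ",
         paste(head(missing, 5), collapse = ", "))
  stopifnot(all(c("gene", "term") %in% names(term_map)))
  tm <- term_map[term_map$gene %in% universe, , drop = FALSE]
  terms <- split(unique(tm)$gene, unique(tm)$term)
  N <- length(universe)
  n <- length(query)
  res <- lapply(names(terms), function(tname) {
    K <- length(terms[[tname]])
    k <- length(intersect(terms[[tname]], query))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tname, term_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, "BH")
  out[order(out$p), , drop = FALSE]
}
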