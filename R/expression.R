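#' Construct an expression matrix
#'
#' Genes x samples values (integer counts or RPKM) together with gene lengths
#' and per-sample condition labels.
#'
#' @param values numeric matrix, rownames = gene ids, colnames = sample names.
#' @param gene_lengths gene model lengths in bp, one per row.
#' @param condition character vector of condition labels, one per column.
#' @param units `"counts"` or `"rpkm"`.
#' @return an `expression_matrix` object (list with `values`, `gene_lengths`,
#'   `condition`, `units`).
#' @export
expression_matrix <- function(values, gene_lengths, condition,
                              units = c("counts", "rpkm")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  stopifnot(length(gene_lengths) == nrow(values),
            length(condition) == ncol(values),
            all(gene_lengths > 0), !is.null(rownames(values)))
  if (any(values < 0)) stop("expression values must be non-negative")
  if (units == "counts" && any(values != floor(values)))
    stop("counts must be integers")
  structure(list(values = values,
                 gene_lengths = setNames(as.numeric(gene_lengths),
                                         rownames(values)),
                 condition = as.character(condition), units = units),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$units))
  cat("conditions:", paste(unique(x$condition), collapse = ", "), "\n")
  invisible(x)
}

#' Convert counts to RPKM
#'
#' `RPKM[g, s] = counts[g, s] * 1e9 / (length_g * library_size_s)`, reads per
#' kilobase of gene model per million mapped reads.
#'
#' @param em an [expression_matrix()] in counts units.
#' @param library_sizes optional per-sample totals; defaults to column sums.
#' @return an `expression_matrix` in RPKM units.
#' @export
rpkm <- function(em, library_sizes = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$units == "rpkm") return(em)
  if (is.null(library_sizes)) library_sizes <- colSums(em$values)
  if (any(library_sizes <= 0)) stop("zero library size")
  vals <- em$values * 1e9 /
    outer(em$gene_lengths, as.numeric(library_sizes))
  expression_matrix(vals, em$gene_lengths, em$condition, units = "rpkm")
}

#' Median/MAD row normalization for heatmap display
#'
#' Per row: subtract the row median and divide by the median absolute
#' deviation (raw MAD, without the 1.4826 Gaussian consistency factor). Rows
#' whose MAD is 0 but which are non-constant after median subtraction are
#' divided by a small epsilon instead; constant rows become all zeros.
#'
#' @param mat numeric matrix (e.g. RPKM of target genes across samples) with
#'   at least 2 columns.
#' @param eps fallback scale for zero-MAD non-constant rows.
#' @return matrix of the same shape with row medians 0.
#' @export
mad_normalize <- function(mat, eps = 1e-8) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("mad_normalize needs >= 2 samples per gene")
  t(apply(mat, 1, function(x) {
    if (length(x) == 0) stop("empty row")
    ctr <- x - median(x)
    m <- median(abs(ctr))
    if (m == 0) {
      if (all(ctr == 0)) return(ctr)
      return(ctr / eps)
    }
    ctr / m
  }))
}

#' Subset an expression matrix to a gene set
#' @param em an [expression_matrix()].
#' @param genes gene ids to keep (order preserved).
#' @return an `expression_matrix` restricted to `genes`.
#' @export
subset_genes <- function(em, genes) {
  genes <- as.character(genes)
  missing <- setdiff(genes, rownames(em$values))
  if (length(missing) > 0)
    stop("genes absent from matrix: ", paste(head(missing, 5), collapse = ", "))
  expression_matrix(em$values[genes, , drop = FALSE], em$gene_lengths[genes],
                    em$condition, em$units)
}

#' Write / read a counts (or RPKM) table as TSV
#'
#' Layout: first column `gene_id`, second `length`, then one column per
#' sample; a `#condition:` comment line records the per-sample labels.
#'
#' @param em an [expression_matrix()].
#' @param path file path.
#' @export
write_counts <- function(em, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#condition:\t", paste(em$condition, collapse = "\t")), con)
  df <- data.frame(gene_id = rownames(em$values), length = em$gene_lengths,
                   em$values, check.names = FALSE)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' @rdname write_counts
#' @param units units of the stored values.
#' @export
read_counts <- function(path, units = "counts") {
  first <- readLines(path, n = 1)
  cond <- NULL
  if (startsWith(first, "#condition:"))
    cond <- strsplit(first, "\t")[[1]][-1]
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(vals) <- df$gene_id
  if (is.null(cond)) cond <- rep("unknown", ncol(vals))
  expression_matrix(vals, df$length, cond, units = units)
}
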