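#' Construct a genome annotation
#'
#' A light container for gene models: one row per gene with 0-based half-open
#' coordinates (BED convention) and a strand, plus the chromosome sizes the
#' coordinates live on. The TSS is the strand-aware 5' end: `start` for `+`
#' genes and `end - 1` for `-` genes.
#'
#' @param gene_id,chrom,start,end,strand parallel vectors describing the genes.
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @return a `genome_annotation` data frame with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand` and a `chrom_sizes` attribute.
#' @export
genome_annotation <- function(gene_id, chrom, start, end, strand, chrom_sizes) {
  df <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    if (anyDuplicated(df$gene_id)) stop("gene_id values must be unique")
    if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (!all(df$chrom %in% names(chrom_sizes)))
      stop("gene on unknown chromosome: ",
           paste(setdiff(df$chrom, names(chrom_sizes)), collapse = ", "))
    lens <- chrom_sizes[df$chrom]
    if (!all(df$start >= 0 & df$start < df$end & df$end <= lens))
      stop("gene coordinates must satisfy 0 <= start < end <= chrom length")
  }
  attr(df, "chrom_sizes") <- chrom_sizes
  class(df) <- c("genome_annotation", "data.frame")
  df
}

#' Chromosome sizes of an annotation or read set
#' @param x a `genome_annotation` or `read_set`.
#' @return named vector of chromosome lengths.
#' @export
chrom_sizes <- function(x) attr(x, "chrom_sizes")

#' Strand-aware TSS positions
#' @param annotation a `genome_annotation`.
#' @return numeric vector of 0-based TSS coordinates, named by gene id.
#' @export
tss_positions <- function(annotation) {
  pos <- ifelse(annotation$strand == "+", annotation$start, annotation$end - 1)
  setNames(pos, annotation$gene_id)
}

#' Construct a ChIP read set
#'
#' Genomic intervals (0-based half-open) for one ChIP factor.
#'
#' @param chrom,start,end parallel vectors of read intervals.
#' @param factor_name factor label, e.g. `"POLII"`, `"CMYC"`, `"SOX2"`.
#' @param chrom_sizes optional named chromosome lengths.
#' @return a `read_set` data frame with a `factor_name` attribute; its
#'   `total_reads` equals the interval count by construction.
#' @export
read_set <- function(chrom, start, end, factor_name, chrom_sizes = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (nrow(df) > 0 && !all(df$start < df$end))
    stop("read intervals must satisfy start < end")
  attr(df, "factor_name") <- factor_name
  attr(df, "chrom_sizes") <- chrom_sizes
  class(df) <- c("read_set", "data.frame")
  df
}

#' @rdname read_set
#' @param x a `read_set`.
#' @export
total_reads <- function(x) nrow(x)

#' @rdname read_set
#' @export
factor_name <- function(x) attr(x, "factor_name")

# internal: GRanges view of 0-based half-open intervals
.as_granges <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1, end = end))
}

#' Write / read a 6-column BED annotation
#'
#' Columns: chrom, start, end, name (gene id), score (0), strand; 0-based
#' half-open. `read_bed6` needs chromosome sizes because BED does not carry
#' them.
#'
#' @param annotation a `genome_annotation`.
#' @param path file path.
#' @export
write_bed6 <- function(annotation, path) {
  df <- data.frame(annotation$chrom, format(annotation$start, scientific = FALSE, trim = TRUE),
                   format(annotation$end, scientific = FALSE, trim = TRUE),
                   annotation$gene_id, 0L, annotation$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed6
#' @param chrom_sizes named chromosome lengths for validation.
#' @export
read_bed6 <- function(path, chrom_sizes) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = c("character", "numeric", "numeric",
                                  "character", "integer", "character"))
  genome_annotation(df[[4]], df[[1]], df[[2]], df[[3]], df[[6]], chrom_sizes)
}

#' Write / read a 3-column BED read file
#' @param readset a `read_set`.
#' @param path file path.
#' @export
write_bed3 <- function(readset, path) {
  df <- data.frame(readset$chrom,
                   format(readset$start, scientific = FALSE, trim = TRUE),
                   format(readset$end, scientific = FALSE, trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed3
#' @param factor_name factor label to attach on read.
#' @param chrom_sizes optional named chromosome lengths.
#' @export
read_bed3 <- function(path, factor_name, chrom_sizes = NULL) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = c("character", "numeric", "numeric"))
  read_set(df[[1]], df[[2]], df[[3]], factor_name, chrom_sizes)
}
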