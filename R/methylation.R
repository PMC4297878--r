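#' Find CpG dinucleotide sites in a sequence
#'
#' @param reference_seq character string over A/C/G/T/N.
#' @return ascending integer vector of 0-based offsets i where `seq[i] == "C"`
#'   and `seq[i+1] == "G"`.
#' @export
find_cpg_sites <- function(reference_seq) {
  s <- strsplit(toupper(reference_seq), "")[[1]]
  n <- length(s)
  if (n < 2) return(integer(0))
  which(s[-n] == "C" & s[-1] == "G") - 1L
}

#' Call methylation states of one bisulfite clone
#'
#' At each CpG site of the (untreated) reference, the bisulfite-converted
#' clone reads C when the cytosine was methylated (protected from conversion)
#' and T when it was unmethylated; any other base is an ambiguous call.
#' Clones must be gapless and equal length to the reference.
#'
#' @param reference_seq reference sequence.
#' @param clone_seq bisulfite-converted clone sequence of equal length.
#' @param sites 0-based CpG offsets (default: computed from the reference).
#' @return character vector over `"M"` (methylated), `"U"` (unmethylated),
#'   `"A"` (ambiguous), one per site, named by site offset.
#' @export
call_clone <- function(reference_seq, clone_seq,
                       sites = find_cpg_sites(reference_seq)) {
  if (nchar(clone_seq) != nchar(reference_seq))
    stop("clone length ", nchar(clone_seq), " != reference length ",
         nchar(reference_seq))
  s <- strsplit(toupper(clone_seq), "")[[1]]
  base <- s[sites + 1]
  call <- ifelse(base == "C", "M", ifelse(base == "T", "U", "A"))
  setNames(call, sites)
}

#' Build a clones x sites methylation matrix
#'
#' @param reference_seq reference sequence.
#' @param clone_seqs character vector (optionally named) of clone sequences.
#' @return a `methylation_matrix`: character matrix of `"M"`/`"U"`/`"A"`
#'   calls, rows = clones, columns = ascending 0-based CpG offsets.
#' @export
call_clones <- function(reference_seq, clone_seqs) {
  sites <- find_cpg_sites(reference_seq)
  rows <- t(vapply(clone_seqs, function(cs)
    call_clone(reference_seq, cs, sites), character(length(sites))))
  if (is.null(rownames(rows)) || any(rownames(rows) == ""))
    rownames(rows) <- sprintf("clone%02d", seq_along(clone_seqs))
  colnames(rows) <- sites
  class(rows) <- c("methylation_matrix", class(rows))
  rows
}

#' Percent methylation of a clone set
#'
#' @param mat a `methylation_matrix` (or any matrix of `"M"`/`"U"`/`"A"`).
#' @return list with `n_methylated`, `n_called` (methylated + unmethylated;
#'   ambiguous calls are excluded from the denominator), and `percent`
#'   (to one decimal).
#' @export
methylation_summary <- function(mat) {
  if (length(mat) == 0) stop("empty methylation matrix")
  nm <- sum(mat == "M")
  nc <- nm + sum(mat == "U")
  if (nc == 0) stop("no called (unambiguous) cells")
  list(n_methylated = nm, n_called = nc, percent = round(100 * nm / nc, 1))
}

#' Lollipop grid of methylation calls
#'
#' @param mat a `methylation_matrix`.
#' @param symbols calls as displayed: methylated, unmethylated, ambiguous.
#' @return character matrix of symbols (rows = clones in input order); collapse
#'   rows with `apply(x, 1, paste, collapse = "")` for a text lollipop plot.
#' @export
lollipop_matrix <- function(mat, symbols = c(M = "●", U = "○",
                                             A = "·")) {
  if (length(mat) == 0)
    return(matrix(character(0), nrow = nrow(mat), ncol = ncol(mat)))
  out <- matrix(symbols[mat], nrow = nrow(mat), dimnames = dimnames(mat))
  out
}

#' Read / write a bisulfite region FASTA
#'
#' First record is the untreated reference, remaining records are clones.
#'
#' @param path FASTA path.
#' @return list with `reference` (string) and `clones` (named character
#'   vector).
#' @export
read_bisulfite_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) < 2) stop("FASTA needs a reference and >= 1 clone")
  list(reference = as.character(seqs[[1]]),
       clones = setNames(as.character(seqs[-1]), names(seqs)[-1]))
}

#' @rdname read_bisulfite_fasta
#' @param reference,clones sequences to write (clones optionally named).
#' @export
write_bisulfite_fasta <- function(reference, clones, path) {
  nm <- names(clones)
  if (is.null(nm)) nm <- sprintf("clone%02d", seq_along(clones))
  set <- Biostrings::DNAStringSet(c(reference = reference,
                                    setNames(clones, nm)))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
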