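#' @importFrom stats quantile rnorm runif setNames
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Plain-character reverse complement; vectorised. Only A/C/G/T/N are
#' expected.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

## Fast path for many strings: route through Biostrings.
revcomp_many <- function(x) {
  if (length(x) < 50L) return(revcomp(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographic minimum of the k-mer
#' and its reverse complement, so both strands share one count record.
#' Ties (true palindromes, only possible for even k) resolve to the k-mer
#' itself, i.e. the plus strand.
#'
#' @param x character vector of k-mers.
#' @return character vector of canonical k-mers.
#' @export
canonical_kmer <- function(x) {
  rc <- revcomp_many(x)
  ifelse(x <= rc, x, rc)
}

## All k-length windows of a single sequence (character vector of windows).
kmer_windows <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

## Number of positions at which two equal-length strings agree.
hamming_matches <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  stopifnot(length(av) == length(bv))
  sum(av == bv)
}

## Random DNA string helper used by the simulator and tests.
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
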