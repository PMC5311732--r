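#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement over plain character vectors. IUPAC
#' ambiguity codes (including N) are handled.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "AAAC"))
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random nucleotide sequence
#'
#' Uniform i.i.d. A/C/G/T string, used for synthetic backgrounds and
#' ancestral element sequences. Uses the current RNG state.
#'
#' @param n length in nt.
#' @return a single character string of length `n`.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# split sequences of equal length into a character matrix (rows = sequences)
.seq_matrix <- function(seqs) {
  stopifnot(length(unique(nchar(seqs))) == 1L)
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE)
}

# internal: message helper that tests can silence
.log <- function(...) message(...)
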