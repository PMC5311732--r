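#' Read a FASTA file into a named character vector
#'
#' Identifiers are truncated at the first whitespace; sequences are
#' uppercased. N is allowed. Duplicate identifiers and empty files are
#' hard errors.
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- toupper(as.character(ss))
  names(out) <- ids
  out
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = 80L)
  invisible(path)
}

#' Dereplicate a FASTQ library into a species table
#'
#' Each distinct read sequence becomes one "species" whose "expression" is
#' the number of reads carrying exactly that sequence. Quality strings are
#' ignored. The sum of expressions equals the number of input reads.
#'
#' @param fastq_path path to an (uncompressed or gzipped) FASTQ file.
#' @return data.frame with columns `sequence`, `length`, `expression`,
#'   ordered by decreasing expression then sequence.
#' @export
dereplicate_reads <- function(fastq_path) {
  if (!file.exists(fastq_path)) stop("FASTQ file not found: ", fastq_path)
  if (file.size(fastq_path) == 0) {
    return(data.frame(sequence = character(0), length = integer(0),
                      expression = integer(0), stringsAsFactors = FALSE))
  }
  n_lines <- length(readLines(fastq_path, warn = FALSE))
  if (n_lines %% 4L != 0L) {
    stop("truncated FASTQ record in ", fastq_path)
  }
  ss <- Biostrings::readDNAStringSet(fastq_path, format = "fastq")
  seqs <- toupper(as.character(ss))
  dt <- data.table(sequence = seqs)[, .(expression = .N), by = sequence]
  dt[, len := nchar(sequence)]
  setorder(dt, -expression, sequence)
  data.frame(sequence = dt$sequence, length = dt$len,
             expression = dt$expression, stringsAsFactors = FALSE)
}

#' Build a species table directly from read sequences
#'
#' Convenience equivalent of [dereplicate_reads()] for in-memory reads.
#'
#' @param reads character vector of read sequences.
#' @return species data.frame as in [dereplicate_reads()].
#' @export
species_table <- function(reads) {
  if (length(reads) == 0L) {
    return(data.frame(sequence = character(0), length = integer(0),
                      expression = integer(0), stringsAsFactors = FALSE))
  }
  dt <- data.table(sequence = toupper(reads))[, .(expression = .N),
                                              by = sequence]
  dt[, len := nchar(sequence)]
  setorder(dt, -expression, sequence)
  data.frame(sequence = dt$sequence, length = dt$len,
             expression = dt$expression, stringsAsFactors = FALSE)
}

#' Write a species table (or raw reads) as FASTQ
#'
#' Each species is emitted `expression` times, with constant dummy
#' qualities, so that [dereplicate_reads()] round-trips the table.
#'
#' @param species species data.frame (`sequence`, `expression`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(species, path) {
  seqs <- rep(species$sequence, species$expression)
  n <- length(seqs)
  ids <- sprintf("read%07d", seq_len(n))
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  quals <- Biostrings::BStringSet(vapply(nchar(seqs), function(k) {
    strrep("I", k)
  }, character(1)))
  Biostrings::writeXStringSet(ss, filepath = path, format = "fastq",
                              qualities = quals)
  invisible(path)
}
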