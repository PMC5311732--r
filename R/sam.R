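#' Import all-hits alignments from a SAM file
#'
#' Reads a SAM file (as produced by an all-hits aligner run, e.g.
#' `bwa aln -n 0` + `bwa samse -n <big>`) and returns one hit per reported
#' zero-mismatch, ungapped, full-length location. Both encodings of
#' additional hits are accepted: separate secondary alignment lines and
#' `XA:Z:` alternative-hit tags. Records with mismatches or indels are
#' skipped and counted, not errors. Hits are deduplicated by
#' (reference, position, strand) per species.
#'
#' @param sam_path path to a SAM file with `@SQ` header lines.
#' @return data.frame of hits with columns `species` (the read sequence,
#'   genome-sense for forward hits), `reference`, `position` (0-based) and
#'   `strand` (`"sense"`/`"antisense"`). The number of skipped non-exact
#'   records is attached as attribute `"skipped"`.
#' @export
import_sam_hits <- function(sam_path) {
  if (!file.exists(sam_path)) stop("SAM file not found: ", sam_path)
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = c("NM", "XA")
  )
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(b$qname)
  if (n == 0L) {
    out <- data.frame(species = character(0), reference = character(0),
                      position = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "skipped") <- 0L
    return(out)
  }
  flag <- b$flag
  mapped <- !bitwAnd(flag, 4L)
  is_primary <- !bitwAnd(flag, 256L) & !bitwAnd(flag, 2048L)
  rev <- bitwAnd(flag, 16L) > 0L

  # original read sequence per query name, from primary lines
  seqs <- as.character(b$seq)
  orig <- ifelse(rev, revcomp(seqs), seqs)
  qseq <- stats::setNames(orig[is_primary & mapped], b$qname[is_primary & mapped])
  # unmapped primaries still carry the sequence
  un <- is_primary & !mapped & !is.na(seqs) & seqs != ""
  qseq <- c(qseq, stats::setNames(orig[un], b$qname[un]))
  qseq <- qseq[!duplicated(names(qseq))]

  nm <- b$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, n)
  exact_cigar <- grepl("^\\d+M$", b$cigar)
  ok <- mapped & exact_cigar & (is.na(nm) | nm == 0L)
  skipped <- sum(mapped & !ok)

  hits <- data.table(
    species = unname(qseq[b$qname[ok]]),
    reference = as.character(b$rname[ok]),
    position = b$pos[ok] - 1L,
    strand = ifelse(rev[ok], "antisense", "sense")
  )

  # XA:Z: alternative hits -- "ref,(+|-)pos,CIGAR,NM;" entries
  xa <- b$tag$XA
  if (!is.null(xa)) {
    wi <- which(!is.na(xa) & nzchar(xa) & mapped)
    if (length(wi)) {
      ent <- strsplit(xa[wi], ";", fixed = TRUE)
      reps <- lengths(ent)
      qn <- rep(b$qname[wi], reps)
      parts <- strsplit(unlist(ent, use.names = FALSE), ",", fixed = TRUE)
      keep <- lengths(parts) == 4L
      parts <- parts[keep]; qn <- qn[keep]
      if (length(parts)) {
        m <- matrix(unlist(parts, use.names = FALSE), ncol = 4L, byrow = TRUE)
        xa_ok <- grepl("^\\d+M$", m[, 3]) & m[, 4] == "0"
        skipped <- skipped + sum(!xa_ok)
        if (any(xa_ok)) {
          posr <- m[xa_ok, 2]
          hits <- rbind(hits, data.table(
            species = unname(qseq[qn[xa_ok]]),
            reference = m[xa_ok, 1],
            position = abs(as.integer(posr)) - 1L,
            strand = ifelse(substr(posr, 1, 1) == "-", "antisense", "sense")
          ))
        }
      }
    }
  }
  hits <- unique(hits)
  setorder(hits, species, reference, position, strand)
  if (skipped > 0) .log("import_sam_hits: skipped ", skipped,
                        " non-exact alignment record(s)")
  out <- as.data.frame(hits)
  attr(out, "skipped") <- as.integer(skipped)
  out
}

#' Write a hit table as an all-hits SAM file
#'
#' One primary line per species (its first hit) with remaining hits
#' encoded in an `XA:Z:` tag, mirroring the output layout of
#' `bwa samse` with all alignments reported. Unmapped species are written
#' as unmapped records.
#'
#' @param hits hit data.frame (`species`, `reference`, `position`,
#'   `strand`), 0-based positions.
#' @param ref_lengths named integer vector of reference lengths for the
#'   `@SQ` header lines.
#' @param path output path.
#' @param species optional character vector of all species sequences;
#'   those without hits are written as unmapped records.
#' @return `path`, invisibly.
#' @export
write_sam <- function(hits, ref_lengths, path, species = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                     as.integer(ref_lengths)), con)
  hd <- data.table(hits)
  all_sp <- unique(c(hd$species, species))
  lines <- character(0)
  for (i in seq_along(all_sp)) {
    sp <- all_sp[i]
    qn <- sprintf("sp%06d", i)
    h <- hd[species == sp]
    if (nrow(h) == 0L) {
      lines <- c(lines, paste(qn, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                              sp, "*", sep = "\t"))
      next
    }
    L <- nchar(sp)
    cig <- sprintf("%dM", L)
    prim <- h[1]
    fl <- if (prim$strand == "antisense") 16L else 0L
    sq <- if (prim$strand == "antisense") revcomp(sp) else sp
    fields <- paste(qn, fl, prim$reference, prim$position + 1L, 0L, cig,
                    "*", 0L, 0L, sq, "*", "NM:i:0", sep = "\t")
    if (nrow(h) > 1L) {
      alt <- h[-1]
      xa <- paste0(alt$reference, ",",
                   ifelse(alt$strand == "antisense", "-", "+"),
                   alt$position + 1L, ",", cig, ",0;", collapse = "")
      fields <- paste0(fields, "\tXA:Z:", xa)
    }
    lines <- c(lines, fields)
  }
  writeLines(lines, con)
  invisible(path)
}
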