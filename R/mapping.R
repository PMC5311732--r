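#' Build an exact-match index over a reference set
#'
#' Hash-style index of every length-L substring of every reference, for
#' each requested read length L. Windows containing N are not indexed
#' (exact matching is over A/C/G/T only). References shorter than the
#' smallest requested length contribute nothing (logged). Species of
#' un-indexed lengths can still be mapped through the per-query scan
#' fallback in [map_species()].
#'
#' @param references named character vector of reference sequences.
#' @param lengths integer vector of read lengths to index,
#'   e.g. `c(21, 22, 24)`.
#' @param set_label label of this reference set (`"genome"`,
#'   `"population"`, `"exemplars"` or custom).
#' @return an object of class `exact_index`.
#' @export
build_index <- function(references, lengths, set_label = "custom") {
  stopifnot(length(lengths) >= 1, all(lengths >= 1))
  if (is.null(names(references)) || anyDuplicated(names(references))) {
    stop("references must be uniquely named")
  }
  references <- toupper(references)
  lengths <- sort(unique(as.integer(lengths)))
  short <- nchar(references) < min(lengths)
  if (any(short)) {
    .log("build_index: ", sum(short),
         " reference(s) shorter than min length not indexed")
  }
  tabs <- vector("list", length(lengths) * length(references))
  k <- 0L
  for (L in lengths) {
    for (ri in seq_along(references)) {
      seqlen <- nchar(references[ri])
      if (seqlen < L) next
      starts <- 0:(seqlen - L)
      kmers <- substring(references[ri], starts + 1L, starts + L)
      keep <- !grepl("N", kmers, fixed = TRUE)
      if (!any(keep)) next
      k <- k + 1L
      tabs[[k]] <- data.table(kmer = kmers[keep],
                              reference = names(references)[ri],
                              position = starts[keep])
    }
  }
  dt <- if (k) rbindlist(tabs[seq_len(k)]) else
    data.table(kmer = character(0), reference = character(0),
               position = integer(0))
  setkey(dt, kmer)
  structure(list(dt = dt, lengths = lengths,
                 ref_lengths = stats::setNames(nchar(references),
                                               names(references)),
                 references = references, set_label = set_label),
            class = "exact_index")
}

#' @export
print.exact_index <- function(x, ...) {
  cat("exact_index [", x$set_label, "]: ", length(x$references),
      " reference(s), lengths {", paste(x$lengths, collapse = ", "),
      "}, ", nrow(x$dt), " indexed windows\n", sep = "")
  invisible(x)
}

# scan fallback: all exact occurrences of `pat` in each reference (sense
# coordinates), used for lengths not in the index (e.g. long mRNA reads)
.scan_occurrences <- function(pat, references) {
  out <- list(); k <- 0L
  for (ri in seq_along(references)) {
    # stepwise regexpr so that overlapping occurrences are all found
    pos <- integer(0)
    start <- 1L
    repeat {
      i <- regexpr(pat, substring(references[ri], start), fixed = TRUE)
      if (i < 0) break
      pos <- c(pos, start + i - 1L)
      start <- start + i
    }
    if (length(pos)) {
      k <- k + 1L
      out[[k]] <- data.table(reference = names(references)[ri],
                             position = pos - 1L)
    }
  }
  if (k) rbindlist(out) else
    data.table(reference = character(0), position = integer(0))
}

#' Map a table of species against an indexed reference set
#'
#' Zero-mismatch, all-hits mapping on both strands. Sense hits are exact
#' occurrences of the species sequence; antisense hits are occurrences of
#' its reverse complement, reported at the occurrence position with
#' `strand = "antisense"`. A reverse-complement palindrome therefore
#' yields both a sense and an antisense hit at the same position (two
#' distinct locations). Species containing N never map.
#'
#' @param species character vector of species sequences (or a species
#'   data.frame with a `sequence` column).
#' @param index an `exact_index` from [build_index()].
#' @return data.frame of hits: `species`, `reference`, `position`
#'   (0-based), `strand`.
#' @export
map_species_table <- function(species, index) {
  if (is.data.frame(species)) species <- species$sequence
  species <- unique(toupper(species))
  if (length(species) == 0L) {
    return(data.frame(species = character(0), reference = character(0),
                      position = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  lens <- nchar(species)
  indexed <- lens %in% index$lengths
  q <- rbind(
    data.table(species = species[indexed], kmer = species[indexed],
               strand = "sense"),
    data.table(species = species[indexed],
               kmer = revcomp(species[indexed]), strand = "antisense")
  )
  res <- index$dt[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  hits <- res[, .(species, reference, position, strand)]
  # scan fallback for un-indexed lengths
  for (sp in species[!indexed]) {
    if (grepl("N", sp, fixed = TRUE)) next
    s <- .scan_occurrences(sp, index$references)
    a <- .scan_occurrences(revcomp(sp), index$references)
    if (nrow(s)) hits <- rbind(hits, data.table(species = sp, s,
                                                strand = "sense"))
    if (nrow(a)) hits <- rbind(hits, data.table(species = sp, a,
                                                strand = "antisense"))
  }
  hits <- unique(hits)
  setorder(hits, species, reference, position, strand)
  as.data.frame(hits)
}

#' Map one species and classify it
#'
#' @param sequence one species sequence.
#' @param index an `exact_index`.
#' @return a `hitset` list: `species`, `set_label`, `hits` (data.frame),
#'   `x` (location count) and `um_tag` (`"U"`, `"M"` or `"unmapped"`).
#' @export
map_species <- function(sequence, index) {
  stopifnot(length(sequence) == 1L)
  hits <- map_species_table(sequence, index)
  x <- nrow(hits)
  structure(list(species = toupper(sequence), set_label = index$set_label,
                 hits = hits, x = x, um_tag = classify_um(x)),
            class = "hitset")
}

#' @export
print.hitset <- function(x, ...) {
  cat("hitset [", x$set_label, "] ", x$species, ": x = ", x$x,
      " (", x$um_tag, ")\n", sep = "")
  invisible(x)
}

#' U/M classification from location counts
#'
#' @param x integer vector of location counts.
#' @return character vector: `"U"` where `x == 1`, `"M"` where `x > 1`,
#'   `"unmapped"` where `x == 0`.
#' @export
classify_um <- function(x) {
  stopifnot(all(x >= 0))
  ifelse(x == 0, "unmapped", ifelse(x == 1, "U", "M"))
}

#' Location counts (x) per species in a reference set
#'
#' @param hits hit data.frame from [map_species_table()].
#' @param species optional character vector (or species data.frame) of all
#'   species; those without hits get `x = 0`.
#' @return data.frame `species`, `x`, `um_tag`.
#' @export
species_locations <- function(hits, species = NULL) {
  if (is.data.frame(species)) species <- species$sequence
  dt <- data.table(hits)[, .(x = .N), by = species]
  if (!is.null(species)) {
    miss <- setdiff(unique(toupper(species)), dt$species)
    if (length(miss)) dt <- rbind(dt, data.table(species = miss, x = 0L))
  }
  setorder(dt, species)
  data.frame(species = dt$species, x = dt$x, um_tag = classify_um(dt$x),
             stringsAsFactors = FALSE)
}

#' Remove blocklisted sequences from a species table
#'
#' Exact full-sequence matching against a blocklist (e.g. known miRNA,
#' tRNA, rRNA and snoRNA sequences), on either strand: a species is
#' removed iff its sequence or its reverse complement equals a blocklist
#' entry.
#'
#' @param species species data.frame (`sequence`, ...).
#' @param blocklist character vector of sequences to remove.
#' @return the filtered species data.frame; the number of removed species
#'   is attached as attribute `"removed"` and logged.
#' @export
filter_blocklist <- function(species, blocklist) {
  block <- unique(toupper(blocklist))
  drop <- species$sequence %in% block | revcomp(species$sequence) %in% block
  if (any(drop)) .log("filter_blocklist: removed ", sum(drop), " species")
  out <- species[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- sum(drop)
  out
}
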