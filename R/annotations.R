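#' TE annotation set
#'
#' Container for annotated elements and their LTR/INT sub-loci. All
#' coordinates are 0-based half-open on the hosting reference sequence.
#'
#' @param elements data.frame with columns `element_id`, `family`,
#'   `reference_id`, `start`, `end`, `strand`.
#' @param sub_loci data.frame with columns `element_id`,
#'   `role` (one of `"LTR5"`, `"INT"`, `"LTR3"`), `start`, `end`. May be
#'   empty.
#' @param ref_lengths optional named integer vector of reference lengths,
#'   used to validate intervals.
#' @return an object of class `te_annotations`.
#' @export
te_annotations <- function(elements, sub_loci = NULL, ref_lengths = NULL) {
  need <- c("element_id", "family", "reference_id", "start", "end", "strand")
  if (!all(need %in% names(elements))) {
    stop("elements must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(sub_loci)) {
    sub_loci <- data.frame(element_id = character(0), role = character(0),
                           start = integer(0), end = integer(0),
                           stringsAsFactors = FALSE)
  }
  elements$start <- as.integer(elements$start)
  elements$end <- as.integer(elements$end)
  if (nrow(sub_loci)) {
    sub_loci$start <- as.integer(sub_loci$start)
    sub_loci$end <- as.integer(sub_loci$end)
  }
  if (any(elements$start < 0) || any(elements$start >= elements$end)) {
    stop("element intervals must satisfy 0 <= start < end")
  }
  if (anyDuplicated(elements$element_id)) stop("duplicate element_id")
  if (!is.null(ref_lengths)) {
    rl <- ref_lengths[elements$reference_id]
    if (any(is.na(rl)) || any(elements$end > rl)) {
      stop("element interval extends beyond its reference sequence")
    }
  }
  if (nrow(sub_loci)) {
    idx <- match(sub_loci$element_id, elements$element_id)
    if (anyNA(idx)) stop("sub-locus refers to unknown element")
    bad <- sub_loci$start < elements$start[idx] |
      sub_loci$end > elements$end[idx] | sub_loci$start >= sub_loci$end
    if (any(bad)) {
      stop("sub-locus interval outside its parent element: ",
           paste(sub_loci$element_id[bad], collapse = ", "))
    }
    # non-overlap within each element
    sl <- data.table(sub_loci)[order(element_id, start)]
    ov <- sl[, any(start[-1] < end[-.N]), by = element_id]$V1
    if (any(ov)) stop("overlapping sub-loci within an element")
  }
  structure(list(elements = as.data.frame(elements),
                 sub_loci = as.data.frame(sub_loci)),
            class = "te_annotations")
}

#' @export
print.te_annotations <- function(x, ...) {
  cat("te_annotations:", nrow(x$elements), "elements,",
      nrow(x$sub_loci), "sub-loci,",
      length(unique(x$elements$family)), "families\n")
  invisible(x)
}

#' Element lengths of an annotation set
#' @param annotations a [te_annotations] object.
#' @return named integer vector (element_id -> length in nt).
#' @export
element_lengths <- function(annotations) {
  with(annotations$elements,
       stats::setNames(as.integer(end - start), element_id))
}

#' Read TE annotations from GFF3
#'
#' Parent features become elements; child features (matched by
#' `ID`/`Parent` attributes) become LTR/INT sub-loci. On-disk GFF3
#' 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention. Roles are taken from a `role` attribute when
#' present; otherwise LTR children are assigned `LTR5`/`LTR3` by position
#' (strand-aware) and any other child becomes `INT`.
#'
#' @param gff_path path to a GFF3 file.
#' @param ref_lengths optional named vector of reference lengths for
#'   validation.
#' @return a [te_annotations] object.
#' @export
read_annotations <- function(gff_path, ref_lengths = NULL) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  par <- if ("Parent" %in% names(mc)) {
    p <- as.list(mc$Parent)
    vapply(p, function(z) if (length(z)) as.character(z[1]) else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else
    sprintf("feature_%d", seq_along(gr))
  fam <- if ("family" %in% names(mc)) as.character(mc$family) else
    as.character(mc$type)
  role <- if ("role" %in% names(mc)) as.character(mc$role) else
    rep(NA_character_, length(gr))

  is_parent <- is.na(par)
  el <- data.frame(
    element_id = ids[is_parent],
    family = fam[is_parent],
    reference_id = as.character(GenomicRanges::seqnames(gr))[is_parent],
    start = GenomicRanges::start(gr)[is_parent] - 1L,
    end = GenomicRanges::end(gr)[is_parent],
    strand = as.character(GenomicRanges::strand(gr))[is_parent],
    stringsAsFactors = FALSE
  )
  el$strand[el$strand == "*"] <- "+"

  ci <- which(!is_parent)
  sl <- data.frame(
    element_id = par[ci],
    role = role[ci],
    type = as.character(S4Vectors::mcols(gr)$type)[ci],
    start = GenomicRanges::start(gr)[ci] - 1L,
    end = GenomicRanges::end(gr)[ci],
    stringsAsFactors = FALSE
  )
  if (nrow(sl) && anyNA(sl$role)) {
    # infer roles from feature type and position
    sl <- do.call(rbind, lapply(split(sl, sl$element_id), function(d) {
      d <- d[order(d$start), ]
      st <- el$strand[match(d$element_id[1], el$element_id)]
      is_ltr <- grepl("terminal_repeat|LTR", d$type, ignore.case = TRUE)
      r <- ifelse(is_ltr, NA_character_, "INT")
      w <- which(is_ltr)
      if (length(w)) {
        if (identical(st, "-")) {
          r[w[1]] <- "LTR3"; if (length(w) > 1) r[w[length(w)]] <- "LTR5"
        } else {
          r[w[1]] <- "LTR5"; if (length(w) > 1) r[w[length(w)]] <- "LTR3"
        }
      }
      d$role <- ifelse(is.na(d$role), r, d$role)
      d
    }))
  }
  sl$type <- NULL
  rownames(sl) <- NULL
  te_annotations(el, sl, ref_lengths = ref_lengths)
}

#' Write TE annotations as GFF3
#'
#' Inverse of [read_annotations()]: internal 0-based half-open intervals
#' are written as 1-based inclusive GFF3, elements as
#' `transposable_element` parents with `family` attributes, sub-loci as
#' children carrying a `role` attribute.
#'
#' @param annotations a [te_annotations] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  el <- annotations$elements
  sl <- annotations$sub_loci
  type_of <- c(LTR5 = "long_terminal_repeat", LTR3 = "long_terminal_repeat",
               INT = "internal_region")
  n_el <- nrow(el); n_sl <- nrow(sl)
  gr <- GenomicRanges::GRanges(
    seqnames = c(el$reference_id,
                 el$reference_id[match(sl$element_id, el$element_id)]),
    ranges = IRanges::IRanges(start = c(el$start, sl$start) + 1L,
                              end = c(el$end, sl$end)),
    strand = c(el$strand,
               el$strand[match(sl$element_id, el$element_id)])
  )
  mc <- S4Vectors::DataFrame(
    source = "tesmap",
    type = c(rep("transposable_element", n_el),
             unname(type_of[sl$role])),
    ID = c(el$element_id, sprintf("%s_%s", sl$element_id, sl$role)),
    family = c(el$family, rep(NA_character_, n_sl)),
    role = c(rep(NA_character_, n_el), sl$role),
    check.names = FALSE
  )
  mc$Parent <- IRanges::CharacterList(
    c(rep(list(character(0)), n_el), as.list(sl$element_id))
  )
  S4Vectors::mcols(gr) <- mc
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
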