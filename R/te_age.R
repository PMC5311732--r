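#' Peaks of an element length distribution
#'
#' Histograms annotated-region lengths at `bin_width` and reports local
#' maxima: bins whose count strictly exceeds both neighbours (bins outside
#' the occupied range count 0) and exceeds `min_prominence`. Full-length
#' elements of a family show up as such peaks. The suggested window is
#' the peak bin plus/minus one bin and is meant to be reviewed and
#' overridden by the analyst.
#'
#' @param lengths numeric vector of annotated-region lengths (nt).
#' @param bin_width histogram bin width (nt).
#' @param min_prominence minimum count for a bin to qualify as a peak.
#' @return data.frame with one row per peak: `mode` (bin midpoint), `low`,
#'   `high` (suggested window bounds, peak bin +/- 1 bin) and `count`
#'   (elements in the peak bin).
#' @export
length_peaks <- function(lengths, bin_width, min_prominence = 0) {
  stopifnot(length(lengths) >= 1, bin_width > 0)
  bin <- floor(lengths / bin_width)
  lo <- min(bin); hi <- max(bin)
  counts <- tabulate(bin - lo + 1L, nbins = hi - lo + 1L)
  padded <- c(0, counts, 0)
  is_peak <- counts > padded[seq_along(counts)] &
    counts > padded[seq_along(counts) + 2L] &
    counts > min_prominence
  idx <- which(is_peak)
  data.frame(
    mode = (lo + idx - 1L) * bin_width + bin_width / 2,
    low = (lo + idx - 2L) * bin_width,
    high = (lo + idx + 1L) * bin_width,
    count = counts[idx]
  )
}

#' Select full-length candidate elements by a length window
#'
#' @param annotations a [te_annotations] object, or a numeric vector of
#'   lengths.
#' @param window numeric `c(low, high)`; elements with length in
#'   `[low, high]` (inclusive) are kept.
#' @return the subsetted [te_annotations] (elements and their sub-loci),
#'   or for a numeric input a logical vector.
#' @export
select_fulllength_candidates <- function(annotations, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (is.numeric(annotations)) {
    return(annotations >= window[1] & annotations <= window[2])
  }
  el <- annotations$elements
  keep <- (el$end - el$start) >= window[1] & (el$end - el$start) <= window[2]
  el <- el[keep, , drop = FALSE]
  sl <- annotations$sub_loci
  sl <- sl[sl$element_id %in% el$element_id, , drop = FALSE]
  rownames(el) <- rownames(sl) <- NULL
  te_annotations(el, sl)
}

#' Global pairwise alignment of an LTR pair
#'
#' Needleman-Wunsch global alignment with affine gap penalties
#' (defaults: match +1, mismatch -1, gap of length g costs
#' `gap_open + g * gap_extend` = 4 + g). Used to align the 5' and 3' LTR
#' of an element before computing divergence. Pre-aligned pairs (equal
#' length, possibly with `-` characters) can instead be passed straight
#' to [ltr_divergence()].
#'
#' @param a,b the two LTR sequences (character scalars).
#' @param match,mismatch,gap_open,gap_extend scoring parameters
#'   (penalties positive).
#' @return list with `aligned_a`, `aligned_b` (gapped strings of equal
#'   length) and `score`.
#' @export
align_ltr_pair <- function(a, b, match = 1, mismatch = -1,
                           gap_open = 4, gap_extend = 1) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  letters <- c("A", "C", "G", "T", "N")
  sm <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(sm) <- match
  sm["N", ] <- mismatch; sm[, "N"] <- mismatch
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
    type = "global", substitutionMatrix = sm,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  list(aligned_a = as.character(Biostrings::alignedPattern(pa)),
       aligned_b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

#' Divergence of an aligned LTR pair
#'
#' Gap columns and columns containing N are excluded from the site count.
#' `p` is the proportion of differing sites; `K` the model-corrected
#' divergence: raw p (`model = "p"`), Jukes-Cantor
#' `K = -(3/4) ln(1 - 4p/3)` (`"JC69"`), or Kimura two-parameter
#' `K = -(1/2) ln(1 - 2P - Q) - (1/4) ln(1 - 2Q)` with transition and
#' transversion proportions P and Q (`"K2P"`). Saturated alignments
#' (log arguments non-positive) yield `K = NA` with a `saturated` flag —
#' never a silently clamped value.
#'
#' @param alignment output of [align_ltr_pair()], or a list/character
#'   vector of two equal-length gapped sequences.
#' @param model `"K2P"` (default), `"JC69"` or `"p"`.
#' @return one-row data.frame: `n_sites`, `n_diff`, `transitions`,
#'   `transversions`, `p_distance`, `model`, `K`, `saturated`.
#' @export
ltr_divergence <- function(alignment, model = c("K2P", "JC69", "p")) {
  model <- match.arg(model)
  if (is.list(alignment) && !is.null(alignment$aligned_a)) {
    s1 <- alignment$aligned_a; s2 <- alignment$aligned_b
  } else {
    s1 <- alignment[[1]]; s2 <- alignment[[2]]
  }
  stopifnot(nchar(s1) == nchar(s2))
  c1 <- strsplit(toupper(s1), "", fixed = TRUE)[[1]]
  c2 <- strsplit(toupper(s2), "", fixed = TRUE)[[1]]
  ok <- c1 %in% c("A", "C", "G", "T") & c2 %in% c("A", "C", "G", "T")
  c1 <- c1[ok]; c2 <- c2[ok]
  n <- length(c1)
  if (n == 0) stop("no comparable sites in alignment")
  diff <- c1 != c2
  purine <- c("A", "G")
  ts <- diff & ((c1 %in% purine) == (c2 %in% purine))
  p <- sum(diff) / n
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  saturated <- FALSE
  K <- switch(model,
    p = p,
    JC69 = {
      if (p >= 0.75) { saturated <- TRUE; NA_real_ }
      else -0.75 * log(1 - 4 * p / 3)
    },
    K2P = {
      if ((1 - 2 * P - Q) <= 0 || (1 - 2 * Q) <= 0) {
        saturated <- TRUE; NA_real_
      } else -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
    }
  )
  data.frame(n_sites = n, n_diff = sum(diff), transitions = sum(ts),
             transversions = sum(diff & !ts), p_distance = p,
             model = model, K = K, saturated = saturated,
             stringsAsFactors = FALSE)
}

#' Insertion age from LTR divergence
#'
#' LTR pairs are identical at insertion and diverge under a molecular
#' clock, so the insertion age is `T = K / (2r)` with divergence `K` and
#' substitution rate `r` (default 1.3e-8 substitutions/site/year).
#'
#' @param K divergence (vectorised; NA propagates).
#' @param r substitution rate per site per year; must be positive.
#' @return age in years.
#' @export
estimate_age <- function(K, r = 1.3e-8) {
  if (r <= 0) stop("substitution rate r must be positive")
  stopifnot(all(is.na(K) | K >= 0))
  K / (2 * r)
}

#' LTR-pair ages for every annotated element
#'
#' Extracts the LTR5/LTR3 sub-loci of each element from the reference
#' sequences, aligns each pair, computes divergence and the insertion
#' age.
#'
#' @param references named character vector holding the annotated
#'   sequences (genome chromosomes).
#' @param annotations a [te_annotations] object with LTR5/LTR3 sub-loci.
#' @param model divergence model, see [ltr_divergence()].
#' @param r substitution rate per site per year.
#' @return data.frame with one row per element that has both LTRs:
#'   `element_id`, `family`, `n_sites`, `p_distance`, `K`, `age_years`.
#' @export
ages_from_annotations <- function(references, annotations, model = "K2P",
                                  r = 1.3e-8) {
  el <- annotations$elements
  sl <- annotations$sub_loci
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(el))) {
    s <- sl[sl$element_id == el$element_id[i], , drop = FALSE]
    l5 <- s[s$role == "LTR5", ]; l3 <- s[s$role == "LTR3", ]
    if (nrow(l5) != 1 || nrow(l3) != 1) next
    refseq <- references[[el$reference_id[i]]]
    a <- substring(refseq, l5$start + 1L, l5$end)
    b <- substring(refseq, l3$start + 1L, l3$end)
    aln <- align_ltr_pair(a, b)
    d <- ltr_divergence(aln, model = model)
    k <- k + 1L
    rows[[k]] <- data.frame(element_id = el$element_id[i],
                            family = el$family[i],
                            n_sites = d$n_sites, p_distance = d$p_distance,
                            K = d$K, age_years = estimate_age(d$K, r),
                            stringsAsFactors = FALSE)
  }
  if (k == 0) stop("no element with both LTR sub-loci annotated")
  do.call(rbind, rows)
}
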