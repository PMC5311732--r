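#' Specification of a synthetic LTR-retrotransposon family
#'
#' Defines the structure and evolutionary parameters of one family:
#' element layout (LTR - INT - LTR), copy number, a hypervariable
#' "palindrome" hotspot inside the LTR, the insertion-age distribution
#' and the substitution rate of the molecular clock.
#'
#' @param name family label.
#' @param copy_number number of genomic copies (>= 1).
#' @param ltr_length,int_length LTR and internal-domain lengths (nt).
#' @param hotspot integer `c(start, end)`, 0-based half-open interval
#'   within the LTR that mutates at an elevated rate (the sRNA-hotspot,
#'   palindrome-rich region).
#' @param age_law `"uniform"` or `"exponential"`.
#' @param age_params for `"uniform"`, `c(min, max)` years; for
#'   `"exponential"`, the mean age in years.
#' @param rate substitution rate r (substitutions/site/year; default
#'   1.3e-8).
#' @param hotspot_factor multiplier on the per-site substitution
#'   probability inside the hotspot (default 5).
#' @return a `family_spec` list.
#' @export
family_spec <- function(name, copy_number, ltr_length = 300L,
                        int_length = 600L,
                        hotspot = c(100L, 160L),
                        age_law = c("uniform", "exponential"),
                        age_params = c(0, 2e6),
                        rate = 1.3e-8, hotspot_factor = 5) {
  age_law <- match.arg(age_law)
  stopifnot(copy_number >= 1, rate > 0, ltr_length >= 1, int_length >= 0,
            hotspot_factor >= 1,
            hotspot[1] >= 0, hotspot[1] < hotspot[2],
            hotspot[2] <= ltr_length)
  structure(list(name = name, copy_number = as.integer(copy_number),
                 ltr_length = as.integer(ltr_length),
                 int_length = as.integer(int_length),
                 hotspot = as.integer(hotspot),
                 age_law = age_law, age_params = age_params,
                 rate = rate, hotspot_factor = hotspot_factor),
            class = "family_spec")
}

# per-site substitution with probability prob (vector over sites)
.mutate_sites <- function(chars, prob) {
  hit <- which(stats::rbinom(length(chars), 1L, pmin(prob, 0.75)) == 1L)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    shift <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- bases[((match(chars[hit], bases) - 1L + shift) %% 4L) + 1L]
  }
  chars
}

#' Simulate the copies of one TE family
#'
#' Builds a random ancestral element (LTR + INT + LTR with identical
#' LTRs), draws an insertion age T for each copy from the family's age
#' distribution, and lets each copy's two LTRs *independently* accumulate
#' substitutions at per-site probability `r * T` (so the expected
#' LTR-LTR divergence is about `2 r T` per site). The INT domain mutates
#' at the same per-site probability; the hotspot interval of each LTR
#' mutates at `hotspot_factor` times that probability, creating the
#' hypervariable columns that N-masked exemplar consensuses show.
#' Substitution-only (no indels), so all copies stay the same length and
#' per-family alignment is positionally trivial.
#'
#' @param spec a [family_spec()].
#' @param seed RNG seed.
#' @return list: `spec`, `elements` (named character vector of copy
#'   sequences), `ages` (years, per copy), `ancestor`, `ltr_length`,
#'   `int_length`, `hotspot`.
#' @export
simulate_family <- function(spec, seed) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(seed)
  Lltr <- spec$ltr_length; Lint <- spec$int_length
  anc_ltr <- strsplit(random_dna(Lltr), "", fixed = TRUE)[[1]]
  anc_int <- if (Lint > 0) strsplit(random_dna(Lint), "", fixed = TRUE)[[1]]
             else character(0)
  ages <- switch(spec$age_law,
    uniform = runif(spec$copy_number, spec$age_params[1], spec$age_params[2]),
    exponential = rexp(spec$copy_number, 1 / spec$age_params[1])
  )
  site_prob <- function(T) {
    p <- rep(spec$rate * T, Lltr)
    hs <- (spec$hotspot[1] + 1L):spec$hotspot[2]
    p[hs] <- p[hs] * spec$hotspot_factor
    p
  }
  elements <- character(spec$copy_number)
  for (i in seq_len(spec$copy_number)) {
    pv <- site_prob(ages[i])
    ltr5 <- .mutate_sites(anc_ltr, pv)
    ltr3 <- .mutate_sites(anc_ltr, pv)
    int <- if (Lint > 0) .mutate_sites(anc_int, rep(spec$rate * ages[i], Lint))
           else character(0)
    elements[i] <- paste(c(ltr5, int, ltr3), collapse = "")
  }
  names(elements) <- sprintf("%s_%03d", spec$name, seq_len(spec$copy_number))
  list(spec = spec, elements = elements, ages = ages,
       ancestor = paste(c(anc_ltr, anc_int, anc_ltr), collapse = ""),
       ltr_length = Lltr, int_length = Lint, hotspot = spec$hotspot)
}

#' Assemble a synthetic genome with nested foreign fragments
#'
#' Places all family copies at non-overlapping random positions on a
#' random background chromosome. With probability `nesting_rate` per
#' element, a fragment of a *different* family (length drawn from a
#' log-normal with the configured median, default 189 nt) replaces the
#' host sequence at a random internal position — sequence replacement
#' rather than insertion keeps every copy of a family the same length, so
#' per-family alignment stays positionally trivial while foreign sequence
#' is still planted for contamination and cross-talk analyses. Emits the
#' genome, a full annotation set (LTR5/INT/LTR3 sub-loci) and a truth
#' table.
#'
#' @param families list of [simulate_family()] results.
#' @param background_length background (inter-element) nt to add; the
#'   chromosome length is this plus the summed element lengths.
#' @param nesting_rate per-element probability of carrying one foreign
#'   fragment.
#' @param seed RNG seed.
#' @param fragment_median median foreign-fragment length (nt).
#' @param fragment_sdlog log-normal sdlog of the fragment length.
#' @param chrom_name chromosome name.
#' @return list of class `synthetic_genome`: `genome` (named character),
#'   `annotations` ([te_annotations]), `truth` (list with `elements` and
#'   `fragments` data.frames), `families`.
#' @export
assemble_genome <- function(families, background_length = 50000L,
                            nesting_rate = 0, seed = 1L,
                            fragment_median = 189L, fragment_sdlog = 0.35,
                            chrom_name = "chr1") {
  set.seed(seed)
  all_seq <- unlist(lapply(families, `[[`, "elements"))
  fam_of <- unlist(lapply(families, function(f)
    rep(f$spec$name, length(f$elements))))
  ages <- unlist(lapply(families, `[[`, "ages"))
  ltr_of <- unlist(lapply(families, function(f)
    rep(f$ltr_length, length(f$elements))))
  int_of <- unlist(lapply(families, function(f)
    rep(f$int_length, length(f$elements))))
  names(fam_of) <- names(ages) <- names(ltr_of) <- names(int_of) <-
    names(all_seq)
  n <- length(all_seq)
  if (n == 0) stop("no elements to place")
  if (background_length < n + 1) {
    stop("insufficient background space for ", n, " elements")
  }

  # nested foreign fragments (replacement, coordinates preserved)
  frag <- list(); fk <- 0L
  fam_names <- unique(fam_of)
  if (nesting_rate > 0 && length(fam_names) >= 2) {
    for (i in seq_len(n)) {
      if (runif(1) > nesting_rate) next
      donor_fam <- sample(setdiff(fam_names, fam_of[i]), 1L)
      donor_el <- sample(names(all_seq)[fam_of == donor_fam], 1L)
      host_len <- nchar(all_seq[i])
      flen <- max(30L, min(round(rlnorm(1, log(fragment_median),
                                        fragment_sdlog)),
                           host_len - 20L,
                           nchar(all_seq[donor_el]) - 1L))
      fstart <- sample.int(host_len - flen - 1L, 1L)      # 0-based, interior
      dstart <- sample.int(nchar(all_seq[donor_el]) - flen, 1L) - 1L
      piece <- substring(all_seq[donor_el], dstart + 1L, dstart + flen)
      all_seq[i] <- paste0(substring(all_seq[i], 1L, fstart), piece,
                           substring(all_seq[i], fstart + flen + 1L,
                                     host_len))
      fk <- fk + 1L
      frag[[fk]] <- data.frame(host = names(all_seq)[i],
                               donor_family = donor_fam,
                               donor_element = donor_el,
                               host_start = fstart,
                               host_end = fstart + flen,
                               length = flen, stringsAsFactors = FALSE)
    }
  }
  fragments <- if (fk) do.call(rbind, frag) else
    data.frame(host = character(0), donor_family = character(0),
               donor_element = character(0), host_start = integer(0),
               host_end = integer(0), length = integer(0),
               stringsAsFactors = FALSE)

  # random placement: split the background into n+1 gaps
  ord <- sample.int(n)
  cuts <- sort(sample.int(background_length - 1L, n))
  gaps <- diff(c(0L, cuts, background_length))
  pieces <- character(2L * n + 1L)
  el_start <- integer(n)
  pos <- 0L
  for (j in seq_len(n)) {
    pieces[2L * j - 1L] <- random_dna(gaps[j])
    pos <- pos + gaps[j]
    el_start[ord[j]] <- pos
    pieces[2L * j] <- all_seq[ord[j]]
    pos <- pos + nchar(all_seq[ord[j]])
  }
  pieces[2L * n + 1L] <- random_dna(gaps[n + 1L])
  genome <- stats::setNames(paste(pieces, collapse = ""), chrom_name)

  el_len <- nchar(all_seq)
  elements <- data.frame(
    element_id = names(all_seq), family = unname(fam_of),
    reference_id = chrom_name, start = el_start,
    end = el_start + el_len, strand = "+",
    age_years = unname(ages), stringsAsFactors = FALSE)
  sub_loci <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- el_start[i]; ll <- ltr_of[i]; il <- int_of[i]
    data.frame(element_id = names(all_seq)[i],
               role = c("LTR5", "INT", "LTR3"),
               start = c(s, s + ll, s + ll + il),
               end = c(s + ll, s + ll + il, s + 2L * ll + il),
               stringsAsFactors = FALSE)
  }))
  sub_loci <- sub_loci[sub_loci$end > sub_loci$start, , drop = FALSE]
  annotations <- te_annotations(
    elements[, c("element_id", "family", "reference_id", "start", "end",
                 "strand")],
    sub_loci, ref_lengths = stats::setNames(nchar(genome), chrom_name))
  # genomic fragment coordinates
  if (nrow(fragments)) {
    off <- el_start[match(fragments$host, names(all_seq))]
    fragments$genome_start <- off + fragments$host_start
    fragments$genome_end <- off + fragments$host_end
  }
  structure(list(genome = genome, annotations = annotations,
                 truth = list(elements = elements, fragments = fragments),
                 families = families),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("synthetic_genome:", nchar(x$genome), "nt,",
      nrow(x$truth$elements), "elements,",
      nrow(x$truth$fragments), "nested fragments\n")
  invisible(x)
}

#' Element sequences of a synthetic genome
#'
#' Extracts each annotated element's sequence from the assembled genome
#' (identical to the stored copy sequences, including any nested
#' fragments).
#'
#' @param sg a `synthetic_genome`.
#' @return named character vector.
#' @export
population_sequences <- function(sg) {
  el <- sg$truth$elements
  stats::setNames(substring(sg$genome[[el$reference_id[1]]],
                            el$start + 1L, el$end),
                  el$element_id)
}

#' Build a family exemplar consensus
#'
#' Column-wise majority consensus over equal-length family copies: a
#' column keeps its majority base if that base's frequency is at least
#' `mask_identity_threshold`, otherwise it is masked as N. Hypervariable
#' hotspot columns therefore come out as contiguous N runs, reproducing
#' the masked palindrome-rich regions seen in real exemplar databases.
#'
#' @param seqs character vector (>= 2) of equal-length sequences.
#' @param mask_identity_threshold minimum majority-base frequency
#'   (default 0.6).
#' @return a single consensus string.
#' @export
build_exemplar <- function(seqs, mask_identity_threshold = 0.6) {
  if (length(seqs) < 2) stop("need at least 2 sequences for a consensus")
  m <- .seq_matrix(toupper(seqs))
  apply_col <- function(col) {
    tb <- table(col)
    b <- names(tb)[which.max(tb)]
    if (max(tb) / length(col) >= mask_identity_threshold) b else "N"
  }
  paste(apply(m, 2, apply_col), collapse = "")
}

#' Silencing model for synthetic sRNA production
#'
#' Describes how elements produce sRNA species: a base production rate
#' per nt for each read length, an exponential decay of production with
#' element age (young, transcriptionally active elements are silenced
#' hardest and map the most sRNAs), a hotspot enrichment factor, and a
#' heavy-tailed expression law (geometric with occasional high-expression
#' outliers) for read counts per species.
#'
#' @param base_rate named numeric vector: expected species per nt of
#'   locus at age 0, per read length.
#' @param decay age-decay rate per year of the production rate.
#' @param hotspot_enrichment sampling weight multiplier for read start
#'   positions overlapping the LTR hotspot (>= 1).
#' @param expr_mean mean of the geometric expression law.
#' @param outlier_prob,outlier_scale probability and multiplier range for
#'   high-expression outlier species.
#' @return a `silencing_model` list.
#' @export
silencing_model <- function(base_rate = c("21" = 0.02, "22" = 0.02,
                                          "24" = 0.08),
                            decay = 1e-6, hotspot_enrichment = 5,
                            expr_mean = 5, outlier_prob = 0.02,
                            outlier_scale = c(50, 400)) {
  stopifnot(all(base_rate >= 0), decay >= 0, hotspot_enrichment >= 1,
            expr_mean > 1)
  structure(list(base_rate = base_rate, decay = decay,
                 hotspot_enrichment = hotspot_enrichment,
                 expr_mean = expr_mean, outlier_prob = outlier_prob,
                 outlier_scale = outlier_scale),
            class = "silencing_model")
}

#' Simulate an sRNA library from a synthetic genome
#'
#' For each element and read length L the number of generated species is
#' Poisson with mean `base_rate[L] * element_length * exp(-decay * T)`
#' (T = insertion age). Start positions are sampled with hotspot
#' positions up-weighted by the enrichment factor; strand is sense or
#' antisense with probability 1/2; every species is a perfect substring
#' of its element (reverse-complemented for antisense). Read counts per
#' species follow the model's expression law. Elements shorter than L are
#' skipped (logged).
#'
#' @param sg a `synthetic_genome` from [assemble_genome()].
#' @param model a [silencing_model()].
#' @param seed RNG seed.
#' @param fastq_path optional path; when given the reads are also written
#'   as FASTQ.
#' @return list: `species` (data.frame `sequence`, `length`,
#'   `expression`) and `truth` (per generated species-instance:
#'   `sequence`, `element_id`, `role`, `strand`, `offset`, `hotspot`).
#' @export
simulate_srna_library <- function(sg, model, seed, fastq_path = NULL) {
  stopifnot(inherits(sg, "synthetic_genome"),
            inherits(model, "silencing_model"))
  set.seed(seed)
  el <- sg$truth$elements
  seqs <- population_sequences(sg)
  fam_by_name <- stats::setNames(sg$families,
                                 vapply(sg$families, function(f) f$spec$name,
                                        character(1)))
  lens <- as.integer(names(model$base_rate))
  rows <- list(); k <- 0L
  skipped <- 0L
  for (i in seq_len(nrow(el))) {
    S <- seqs[[el$element_id[i]]]
    Lel <- nchar(S)
    fam <- fam_by_name[[el$family[i]]]
    hs <- fam$hotspot; lltr <- fam$ltr_length; lint <- fam$int_length
    # hotspot start-position intervals in element coordinates (both LTRs)
    hot1 <- c(hs[1], hs[2])
    hot2 <- c(lltr + lint + hs[1], lltr + lint + hs[2])
    for (L in lens) {
      if (Lel < L) { skipped <- skipped + 1L; next }
      lambda <- model$base_rate[[as.character(L)]] * Lel *
        exp(-model$decay * el$age_years[i])
      nsp <- rpois(1L, lambda)
      if (nsp == 0L) next
      starts0 <- 0:(Lel - L)
      w <- rep(1, length(starts0))
      overlaps <- function(a, b) starts0 + L > a & starts0 < b
      w[overlaps(hot1[1], hot1[2]) | overlaps(hot2[1], hot2[2])] <-
        model$hotspot_enrichment
      off <- sample(starts0, nsp, replace = TRUE, prob = w)
      strand <- ifelse(runif(nsp) < 0.5, "sense", "antisense")
      sub <- substring(S, off + 1L, off + L)
      seqr <- ifelse(strand == "sense", sub, revcomp(sub))
      role <- ifelse(off + L <= lltr, "LTR5",
              ifelse(off >= lltr + lint & off + L <= 2L * lltr + lint,
                     "LTR3",
              ifelse(off >= lltr & off + L <= lltr + lint, "INT",
                     "boundary")))
      hot <- overlaps(hot1[1], hot1[2])[off + 1L] |
        overlaps(hot2[1], hot2[2])[off + 1L]
      k <- k + 1L
      rows[[k]] <- data.frame(sequence = seqr,
                              element_id = el$element_id[i],
                              role = role, strand = strand, offset = off,
                              length = L, hotspot = hot,
                              stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0) .log("simulate_srna_library: skipped ", skipped,
                        " element x length combinations (element too short)")
  truth <- if (k) do.call(rbind, rows) else
    data.frame(sequence = character(0), element_id = character(0),
               role = character(0), strand = character(0),
               offset = integer(0), length = integer(0),
               hotspot = logical(0), stringsAsFactors = FALSE)
  uniq <- unique(truth$sequence)
  expr <- .draw_expression(length(uniq), model)
  species <- data.frame(sequence = uniq, length = nchar(uniq),
                        expression = expr, stringsAsFactors = FALSE)
  if (!is.null(fastq_path)) write_fastq(species, fastq_path)
  list(species = species, truth = truth)
}

.draw_expression <- function(n, model) {
  if (n == 0) return(integer(0))
  e <- rgeom(n, prob = 1 / model$expr_mean) + 1L
  out <- runif(n) < model$outlier_prob
  if (any(out)) {
    e[out] <- e[out] * round(runif(sum(out), model$outlier_scale[1],
                                   model$outlier_scale[2]))
  }
  as.integer(e)
}
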