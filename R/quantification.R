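#' Attach multi-mapping weights to hits
#'
#' Under the unweighted scheme every location gets weight 1. Under the
#' weighted scheme every location of a species gets weight 1/x, where x is
#' the species' total number of locations in the *denominator* reference
#' set — which may differ from the set the hits are tallied on (e.g.
#' genome-weighted tallies on an annotated TE population). Expression
#' tallies use `expression * weight` per hit.
#'
#' @param hits hit data.frame (`species`, `reference`, `position`,
#'   `strand`).
#' @param scheme `"unweighted"` or `"weighted"`.
#' @param denominator_x for the weighted scheme, the x table of the
#'   denominator set ([species_locations()] output, or a named numeric
#'   vector species -> x).
#' @return the hits data.frame with an added `weight` column.
#' @export
weight_hits <- function(hits, scheme = c("unweighted", "weighted"),
                        denominator_x = NULL) {
  scheme <- match.arg(scheme)
  hits <- as.data.frame(hits)
  if (scheme == "unweighted") {
    hits$weight <- 1.0
    return(hits)
  }
  if (is.null(denominator_x)) {
    stop("weighted scheme requires denominator_x")
  }
  if (is.data.frame(denominator_x)) {
    xv <- stats::setNames(denominator_x$x, denominator_x$species)
  } else xv <- denominator_x
  x <- unname(xv[hits$species])
  if (anyNA(x) || any(x == 0)) {
    stop("species unmapped in the denominator reference set: ",
         paste(utils::head(unique(hits$species[is.na(x) | x == 0]), 5),
               collapse = ", "))
  }
  hits$weight <- 1 / x
  hits
}

# hits fully contained in a locus; adds species length and expression
.hits_in_locus <- function(hits, species_tab, locus) {
  dt <- data.table(hits)
  dt[, len := nchar(species)]
  dt <- dt[reference == locus$reference & position >= locus$start &
             position + len <= locus$end]
  if (!is.null(species_tab)) {
    ex <- data.table(species = species_tab$sequence,
                     expression = species_tab$expression)
    dt <- ex[dt, on = "species"]
  } else dt[, expression := NA_integer_]
  dt
}

#' Per-locus species and expression metrics
#'
#' For a locus (full element, LTR or INT domain) computes the distinct
#' species count and the per-nucleotide species and expression densities
#' under the weighting carried by `hits$weight`. A hit belongs to the
#' locus iff its full read span lies inside the locus interval.
#'
#' `species_count` counts each distinct species once. `species_per_nt` is
#' `species_count / length` under the unweighted scheme; under a weighted
#' scheme it is the sum of per-hit weights (1/x) over in-locus hits
#' divided by length (each species contributes its in-locus share of
#' itself). `expression_per_nt` is the sum of `expression * weight` over
#' in-locus hits divided by length under either scheme.
#'
#' @param hits weighted hit data.frame from [weight_hits()].
#' @param species_tab species data.frame (`sequence`, `expression`).
#' @param locus list or one-row data.frame with `reference`, `start`,
#'   `end` (0-based half-open).
#' @param scheme label recorded in the output (`"unweighted"` or a
#'   weighted-denominator label).
#' @param element_id,role labels recorded in the output.
#' @return one-row data.frame of locus metrics.
#' @export
locus_metrics <- function(hits, species_tab, locus,
                          scheme = "unweighted",
                          element_id = NA_character_, role = "full") {
  L <- locus$end - locus$start
  if (L <= 0) stop("zero-length locus")
  if (is.null(hits$weight)) stop("hits must carry weights; see weight_hits()")
  dt <- .hits_in_locus(hits, species_tab, locus)
  species_count <- length(unique(dt$species))
  unweighted <- all(dt$weight == 1)
  species_mass <- if (nrow(dt) == 0) 0 else
    if (unweighted) species_count else sum(dt$weight)
  expr_mass <- if (nrow(dt) == 0) 0 else sum(dt$expression * dt$weight)
  data.frame(element_id = element_id, role = role, length = L,
             species_count = species_count,
             species_per_nt = species_mass / L,
             expression_per_nt = expr_mass / L,
             scheme = scheme, stringsAsFactors = FALSE)
}

#' Metrics for every element (and optionally sub-locus) of an annotation set
#'
#' @param annotations a [te_annotations] object.
#' @param hits weighted hit data.frame.
#' @param species_tab species data.frame.
#' @param scheme label recorded in the output.
#' @param roles which loci to compute: `"full"` and/or sub-locus roles
#'   (`"LTR5"`, `"INT"`, `"LTR3"`).
#' @return data.frame, one row per element x role.
#' @export
element_metrics <- function(annotations, hits, species_tab,
                            scheme = "unweighted", roles = "full") {
  el <- annotations$elements
  sl <- annotations$sub_loci
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(el))) {
    if ("full" %in% roles) {
      k <- k + 1L
      rows[[k]] <- locus_metrics(hits, species_tab,
                                 list(reference = el$reference_id[i],
                                      start = el$start[i], end = el$end[i]),
                                 scheme, el$element_id[i], "full")
    }
    sli <- sl[sl$element_id == el$element_id[i] & sl$role %in% roles, ,
              drop = FALSE]
    for (j in seq_len(nrow(sli))) {
      k <- k + 1L
      rows[[k]] <- locus_metrics(hits, species_tab,
                                 list(reference = el$reference_id[i],
                                      start = sli$start[j],
                                      end = sli$end[j]),
                                 scheme, el$element_id[i], sli$role[j])
    }
  }
  do.call(rbind, rows)
}

#' Fast per-reference densities
#'
#' When each reference sequence *is* a locus (mapping against an annotated
#' population where every element is its own reference), per-element
#' metrics reduce to a group-by over references. Equivalent to
#' [locus_metrics()] on the whole-reference locus.
#'
#' @param hits weighted hit data.frame.
#' @param species_tab species data.frame.
#' @param ref_lengths named vector of reference lengths.
#' @param scheme label recorded in the output.
#' @return data.frame, one row per reference (references with no hits get
#'   zero densities).
#' @export
density_per_reference <- function(hits, species_tab, ref_lengths,
                                  scheme = "unweighted") {
  dt <- data.table(hits)
  ex <- data.table(species = species_tab$sequence,
                   expression = species_tab$expression)
  dt <- ex[dt, on = "species"]
  unweighted <- all(dt$weight == 1)
  agg <- dt[, .(species_count = uniqueN(species),
                species_mass = if (unweighted) as.numeric(uniqueN(species))
                               else sum(weight),
                expr_mass = sum(expression * weight)),
            by = reference]
  out <- data.table(reference = names(ref_lengths),
                    length = as.integer(ref_lengths))
  out <- agg[out, on = "reference"]
  for (cn in c("species_count", "species_mass", "expr_mass")) {
    set(out, which(is.na(out[[cn]])), cn, 0)
  }
  out[, `:=`(species_per_nt = species_mass / length,
             expression_per_nt = expr_mass / length,
             scheme = scheme)]
  out[, species_mass := NULL][, expr_mass := NULL]
  setorder(out, reference)
  as.data.frame(out)
}

#' Strand-resolved windowed density profile of a locus
#'
#' Splits the locus into `n_windows` contiguous windows whose sizes differ
#' by at most 1 nt and sum to the locus length (the first `L %% n` windows
#' take the extra nucleotide). Each in-locus hit is assigned to the window
#' containing its 5'-most coordinate within the locus: the hit start for
#' sense hits, the hit end - 1 for antisense hits. Species densities count
#' species occurrences (weighted by the scheme); expression densities sum
#' `expression * weight`. Densities are per nucleotide of window,
#' separately by strand, so `density * window length` summed over windows
#' and strands reproduces the locus totals exactly.
#'
#' @inheritParams locus_metrics
#' @param n_windows number of windows (default 100).
#' @return data.frame with one row per window x strand: `window`
#'   (1-based), `win_start` (locus-relative 0-based), `win_length`,
#'   `strand`, `species_density`, `expression_density`.
#' @export
window_profile <- function(hits, species_tab, locus, n_windows = 100L,
                           scheme = "unweighted",
                           element_id = NA_character_, role = "full") {
  L <- locus$end - locus$start
  n <- as.integer(n_windows)
  if (L < n) {
    stop("locus length (", L, ") is shorter than n_windows (", n,
         "); choose a smaller n_windows")
  }
  sizes <- rep(L %/% n, n)
  r <- L %% n
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  starts <- cumsum(c(0L, sizes[-n]))

  dt <- .hits_in_locus(hits, species_tab, locus)
  grid <- data.table(expand.grid(window = seq_len(n),
                                 strand = c("sense", "antisense"),
                                 stringsAsFactors = FALSE))
  if (nrow(dt)) {
    off5 <- ifelse(dt$strand == "sense",
                   dt$position - locus$start,
                   dt$position + dt$len - 1L - locus$start)
    dt[, win := findInterval(off5, starts)]
    agg <- dt[, .(species_mass = sum(weight),
                  expr_mass = sum(expression * weight)),
              by = .(window = win, strand)]
    grid <- agg[grid, on = c("window", "strand")]
  } else {
    grid[, `:=`(species_mass = 0, expr_mass = 0)]
  }
  for (cn in c("species_mass", "expr_mass")) {
    set(grid, which(is.na(grid[[cn]])), cn, 0)
  }
  grid[, `:=`(win_start = starts[window], win_length = sizes[window])]
  grid[, `:=`(species_density = species_mass / win_length,
              expression_density = expr_mass / win_length)]
  grid[, `:=`(species_mass = NULL, expr_mass = NULL)]
  setorder(grid, strand, window)
  out <- as.data.frame(grid[, .(window, win_start, win_length, strand,
                                species_density, expression_density)])
  attr(out, "element_id") <- element_id
  attr(out, "role") <- role
  attr(out, "scheme") <- scheme
  out
}

#' U/M composition of a mapped species set
#'
#' Proportions are over mapped species only; with zero mapped species the
#' proportions are reported as missing (NA), not 0.
#'
#' @param x integer vector of per-species location counts in one
#'   reference set ([species_locations()] `x` column).
#' @return list with `n_mapped`, `U`, `M`, `prop_U`, `prop_M`.
#' @export
um_ratio <- function(x) {
  stopifnot(all(x >= 0))
  U <- sum(x == 1); M <- sum(x > 1); n <- U + M
  list(n_mapped = n, U = U, M = M,
       prop_U = if (n > 0) U / n else NA_real_,
       prop_M = if (n > 0) M / n else NA_real_)
}
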