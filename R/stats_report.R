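#' Cross-talk arithmetic for one family pair
#'
#' Given the number of species mapped to family A, to family B and to
#' both, the non-redundant species count is
#' `mapped_A + mapped_B - shared` and the cross-talk percentage is
#' `100 * shared / non_redundant`. Any sufficient subset of the counts
#' may be supplied (e.g. the combined sum and the shared count).
#'
#' @param shared species mapping to both families.
#' @param mapped_a,mapped_b species mapping to each family (with >= 1
#'   hit).
#' @param sum_ab `mapped_a + mapped_b`, if the addends are not known
#'   individually.
#' @param non_redundant `sum_ab - shared`, if already known.
#' @param family_a,family_b labels.
#' @return one-row data.frame: `family_a`, `family_b`, `mapped_a`,
#'   `mapped_b`, `sum_ab`, `shared`, `non_redundant`, `crosstalk_pct`
#'   (unrounded; round at display).
#' @export
crosstalk_cell <- function(shared, mapped_a = NA, mapped_b = NA,
                           sum_ab = NULL, non_redundant = NULL,
                           family_a = "A", family_b = "B") {
  if (is.null(sum_ab)) {
    if (!is.null(non_redundant)) sum_ab <- non_redundant + shared
    else if (!is.na(mapped_a) && !is.na(mapped_b)) sum_ab <- mapped_a + mapped_b
    else stop("need sum_ab, non_redundant, or both mapped counts")
  }
  if (is.null(non_redundant)) non_redundant <- sum_ab - shared
  stopifnot(shared >= 0, non_redundant >= 0, sum_ab == non_redundant + shared)
  if (!is.na(mapped_a) && !is.na(mapped_b)) {
    stopifnot(shared <= min(mapped_a, mapped_b),
              non_redundant >= max(mapped_a, mapped_b))
  }
  pct <- if (non_redundant > 0) 100 * shared / non_redundant else NA_real_
  data.frame(family_a = family_a, family_b = family_b,
             mapped_a = mapped_a, mapped_b = mapped_b, sum_ab = sum_ab,
             shared = shared, non_redundant = non_redundant,
             crosstalk_pct = pct, stringsAsFactors = FALSE)
}

#' Family cross-talk from a hit table
#'
#' For every unordered family pair, counts the species mapping to each
#' family, the species shared by both, and the cross-talk percentage over
#' the non-redundant species pool. High cross-talk between families is a
#' signature of foreign-fragment contamination of the annotated
#' populations.
#'
#' @param hits hit data.frame (`species`, `reference`).
#' @param ref_families named character vector mapping each reference id
#'   to its family.
#' @return data.frame of [crosstalk_cell()] rows, one per family pair.
#' @export
crosstalk <- function(hits, ref_families) {
  fam <- unname(ref_families[hits$reference])
  if (anyNA(fam)) stop("hit on a reference with unknown family")
  sets <- lapply(split(hits$species, fam), unique)
  fams <- sort(names(sets))
  if (length(fams) < 2) stop("need at least two families")
  pairs <- utils::combn(fams, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    crosstalk_cell(shared = length(intersect(sets[[a]], sets[[b]])),
                   mapped_a = length(sets[[a]]),
                   mapped_b = length(sets[[b]]),
                   family_a = a, family_b = b)
  })
  do.call(rbind, rows)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Ranks use average-rank tie handling. The p-value uses the
#' t-distribution approximation `t = r * sqrt((n-2)/(1-r^2))` on `n - 2`
#' degrees of freedom; for very small samples (`n <= 8`) an exact
#' permutation p-value can be requested instead (all `n!` permutations
#' are enumerated). A constant input vector has no defined rank
#' correlation and is reported as missing.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`.
#' @param method `"tapprox"` (default) or `"exact"`.
#' @return list: `n`, `r`, `p`, `method`.
#' @export
rank_correlation <- function(x, y, method = c("tapprox", "exact")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(n = n, r = NA_real_, p = NA_real_, method = method))
  }
  r <- stats::cor(rx, ry)
  if (method == "exact") {
    if (n > 8) stop("exact permutation p-value supported for n <= 8")
    perms <- .permutations(n)
    rs <- apply(perms, 1, function(pp) stats::cor(rx, ry[pp]))
    p <- mean(abs(rs) >= abs(r) - 1e-12)
  } else {
    if (abs(r) >= 1) {
      p <- 0
    } else {
      tval <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tval), df = n - 2)
    }
  }
  list(n = n, r = r, p = p, method = method)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Expression-dominance ("zoning") diagnostic
#'
#' Detects the situation where a single very highly expressed species
#' splits a family's elements into two expression zones. Per element the
#' dominance of the top species (its share of the element's total
#' unweighted expression) is reported; the population is split into
#' upper/lower groups at the threshold on log10 total expression that
#' maximises the between-group variance; and the flag is raised when the
#' ratio of group medians is at least `split_factor` but drops below it
#' once the single top species (highest summed expression across
#' elements) is removed.
#'
#' @param contrib data.frame of per-element per-species expression
#'   contributions: columns `element_id`, `species`, `expression`.
#' @param split_factor minimum upper/lower median ratio for a split to
#'   count (default 1.5).
#' @return list with `per_element` (element_id, total, top_species,
#'   top_expression, dominance, group) and `split` (threshold,
#'   ratio_before, ratio_after, top_species, flag).
#' @export
dominance_diagnostic <- function(contrib, split_factor = 1.5) {
  dt <- data.table(contrib)[expression > 0]
  per <- dt[, .(total = sum(expression),
                top_species = species[which.max(expression)],
                top_expression = max(expression)),
            by = element_id]
  per[, dominance := top_expression / total]
  if (nrow(per) == 0) stop("no element with positive expression")

  split1 <- .otsu_split(log10(per$total))
  per[, group := ifelse(log10(total) > split1$threshold, "upper", "lower")]
  ratio_before <- .group_median_ratio(per$total, per$group)

  top_overall <- dt[, .(s = sum(expression)), by = species][which.max(s),
                                                            species]
  dt2 <- dt[species != top_overall]
  per2 <- dt2[, .(total = sum(expression)), by = element_id]
  ratio_after <- if (nrow(per2) >= 2) {
    sp2 <- .otsu_split(log10(per2$total))
    g2 <- ifelse(log10(per2$total) > sp2$threshold, "upper", "lower")
    .group_median_ratio(per2$total, g2)
  } else NA_real_

  flag <- isTRUE(ratio_before >= split_factor) &&
    (is.na(ratio_after) || ratio_after < split_factor)
  list(per_element = as.data.frame(per),
       split = list(threshold = split1$threshold,
                    ratio_before = ratio_before,
                    ratio_after = ratio_after,
                    top_species = top_overall, flag = flag))
}

# 1-D two-group split maximising between-group variance (Otsu)
.otsu_split <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n < 2 || length(unique(v)) == 1) {
    return(list(threshold = v[1], between_var = 0))
  }
  best <- -Inf; thr <- v[1]
  for (k in seq_len(n - 1)) {
    if (v[k] == v[k + 1]) next
    w1 <- k / n; w2 <- 1 - w1
    bv <- w1 * w2 * (mean(v[seq_len(k)]) - mean(v[(k + 1):n]))^2
    if (bv > best) { best <- bv; thr <- (v[k] + v[k + 1]) / 2 }
  }
  list(threshold = thr, between_var = best)
}

# ratio of group medians; a degenerate split (one group empty, e.g. all
# totals equal) means the population does not separate -> ratio 1
.group_median_ratio <- function(total, group) {
  up <- total[group == "upper"]; lo <- total[group == "lower"]
  if (!length(up) || !length(lo)) return(1)
  stats::median(up) / stats::median(lo)
}

#' Location-count summaries for multi-mappers
#'
#' Median and mean number of mapping locations (x) per category, over
#' multi-mapping species only (`x >= 2`). Categories with no
#' multi-mappers get missing values.
#'
#' @param x integer vector of location counts.
#' @param category character vector of the same length assigning each
#'   species to a category.
#' @return data.frame: `category`, `n_m`, `median_x`, `mean_x`.
#' @export
location_summary <- function(x, category) {
  stopifnot(length(x) == length(category))
  dt <- data.table(x = as.numeric(x), category = category)[x >= 2]
  out <- dt[, .(n_m = .N, median_x = stats::median(x),
                mean_x = mean(x)), by = category]
  all_cat <- unique(category)
  miss <- setdiff(all_cat, out$category)
  if (length(miss)) {
    out <- rbind(out, data.table(category = miss, n_m = 0L,
                                 median_x = NA_real_, mean_x = NA_real_))
  }
  setorder(out, category)
  as.data.frame(out)
}
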