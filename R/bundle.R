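#' Standard synthetic study bundle
#'
#' One call builds the full desk-scale study system: three LTR-TE families
#' of differing copy number, a genome with the copies placed on a random
#' background (optionally carrying nested foreign fragments), per-family
#' N-masked exemplar consensuses, and a simulated sRNA library with its
#' truth table.
#'
#' Default conditions: 200 elements over three families (90/70/40 copies),
#' 300 nt LTRs with a 60 nt hypervariable hotspot mutating at 25x the
#' clock rate, 600 nt internal domains, insertion ages uniform on
#' 0.5-3 My, substitution rate 1.3e-8/site/year, exemplar mask threshold
#' 0.9, and the default [silencing_model()] (24 nt-dominated production
#' decaying with age at 1e-6/year). The hotspot factor and mask threshold
#' are set so that, under the substitution clock at these ages, hotspot
#' consensus columns fall below the mask threshold and non-hotspot columns
#' stay above it (giving contiguous N runs over the hotspot), which the
#' 5x / 0.6 combination cannot achieve at My-scale ages.
#'
#' @param seed RNG seed; sub-seeds for each stage are derived from it.
#' @param n_copies integer vector of per-family copy numbers.
#' @param ltr_length,int_length element layout (nt).
#' @param hotspot hotspot interval within the LTR (0-based half-open).
#' @param age_range insertion-age range (years), uniform.
#' @param rate substitution rate (per site per year).
#' @param hotspot_factor hotspot mutation multiplier.
#' @param nesting_rate per-element probability of a nested foreign
#'   fragment.
#' @param background_length background nt between elements.
#' @param mask_threshold exemplar consensus mask threshold.
#' @param model a [silencing_model()].
#' @return list: `sg` (synthetic_genome), `population` (element
#'   sequences), `exemplars` (one consensus per family), `library`
#'   (species + truth), `ages` (element_id, family, age_years),
#'   `families`.
#' @export
synthetic_bundle <- function(seed,
                             n_copies = c(90L, 70L, 40L),
                             ltr_length = 300L, int_length = 600L,
                             hotspot = c(100L, 160L),
                             age_range = c(5e5, 3e6),
                             rate = 1.3e-8, hotspot_factor = 25,
                             nesting_rate = 0,
                             background_length = 60000L,
                             mask_threshold = 0.9,
                             model = silencing_model()) {
  fam_names <- paste0("fam", LETTERS[seq_along(n_copies)])
  fams <- lapply(seq_along(n_copies), function(i) {
    simulate_family(
      family_spec(fam_names[i], n_copies[i], ltr_length, int_length,
                  hotspot = hotspot, age_law = "uniform",
                  age_params = age_range, rate = rate,
                  hotspot_factor = hotspot_factor),
      seed = seed * 13L + i)
  })
  sg <- assemble_genome(fams, background_length = background_length,
                        nesting_rate = nesting_rate, seed = seed * 7L + 1L)
  pop <- population_sequences(sg)
  fam_of <- stats::setNames(sg$truth$elements$family,
                            sg$truth$elements$element_id)
  exemplars <- vapply(fam_names, function(fn) {
    build_exemplar(pop[fam_of[names(pop)] == fn], mask_threshold)
  }, character(1))
  lib <- simulate_srna_library(sg, model, seed = seed * 3L + 2L)
  ages <- sg$truth$elements[, c("element_id", "family", "age_years")]
  list(sg = sg, population = pop, exemplars = exemplars, library = lib,
       ages = ages, families = fams)
}
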