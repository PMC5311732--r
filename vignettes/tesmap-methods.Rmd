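---
title: "Methods: small-RNA quantification on transposable elements with tesmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA quantification on transposable elements with tesmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tesmap)
```

## The problem

Small RNAs (siRNAs of 21, 22 and 24 nt in plants) direct the epigenetic
silencing of transposable elements (TEs). Quantifying them against TE
references is methodologically treacherous for three reasons that this
package makes explicit and measurable:

1. **Multi-mapping.** TE families have hundreds to thousands of
   near-identical genomic copies, so most TE-derived sRNA reads map to many
   locations. How multi-mappers (M_sRNAs) are counted — every location as
   1, or each location down-weighted to 1/x where x is the read's total
   number of locations — can qualitatively change downstream biology.
2. **Choice of reference.** Mapping to family *exemplars* (one consensus
   per family) behaves very differently from mapping to the *annotated
   population* of individual full-length elements, and exemplars may carry
   long N-masked stretches where the family is too variable to resolve.
3. **Annotation contamination.** Annotated elements often harbour nested
   fragments of *other* TE families, which inflates the apparent sharing
   of sRNAs between families ("cross-talk").

The unit of analysis is the sequence **species**: a distinct read sequence,
whose **expression** is its read count. Every species is mapped
exhaustively with zero mismatches and tagged **U** (one location) or **M**
(more than one), independently per reference set.

## Core definitions

For a species with x locations in the chosen *denominator* reference set,
the weighted scheme assigns each location the value 1/x (expression
contributes expression/x per location); the unweighted scheme assigns 1.
Per locus (full element, LTR, or internal domain) we report:

* `species_count` — distinct species with at least one fully-contained hit;
* `species_per_nt` — unweighted: `species_count / length`; weighted: the
  sum of 1/x over in-locus hits divided by length. The weighted-species
  convention is not uniquely determined by common usage, so the scheme
  label travels with every output row;
* `expression_per_nt` — the sum of `expression * weight` over in-locus
  hits divided by length.

A hit belongs to a locus only if its **full read span** lies inside the
locus. This avoids double counting at LTR/INT borders; boundary-spanning
reads count for the full element but for neither sub-locus.

Windowed profiles split a locus into `n` (default 100) contiguous windows
whose sizes differ by at most 1 nt; each hit is assigned to the window
holding its 5'-most in-locus coordinate (hit start on the sense strand,
hit end − 1 on the antisense strand). Window species densities count
species *occurrences* (hits, under the active weighting), not distinct
species, so that `density × window length`, summed over windows and
strands, reproduces the locus totals exactly — a conservation law the test
suite asserts to 1e-9.

Insertion ages come from the LTR pair of each element: the two LTRs are
identical at insertion and diverge under a molecular clock, so
`T = K / (2r)` with divergence K and substitution rate
`r = 1.3e-8` substitutions/site/year. K is computed from a global
pairwise alignment of the two LTRs (gap columns and N columns excluded)
under raw p-distance, Jukes–Cantor 1969, or Kimura 2-parameter (default)
correction. Saturated alignments return an explicit missing K — never a
clamped value. The correction model is a user-facing parameter and is
recorded in the output, because published workflows rarely print it.

Cross-talk between families A and B is
`100 × shared / (mapped_A + mapped_B − shared)`, the percentage of the
non-redundant species pool mapping to both. The contamination screen that
explains inflated cross-talk is an exact-seed (20-mer) ungapped
extension: scoring is match +1, mismatch −min_identity/(1−min_identity)
(so a segment scores positively only above the identity floor), each
direction extends with an X-drop stop and trims back to its best-scoring
endpoint, overlapping matches per host/donor-family pair are merged, and
matches of at least `min_match` (default 100 nt) are reported. A planted
verbatim fragment of at least `max(min_match, seed)` nt is therefore
always recovered at identity ~1. Externally computed BLASTN tabular hits
can be imported instead and filtered at E ≤ 1e-20, preserving the
conventional workflow.

## The synthetic data generator

Real maize-scale inputs (a 2.3 Gb genome, GEO sRNA libraries, curated
family databases) are far beyond desk scale, so the package ships a
generator that reproduces the *statistical structure* those analyses rely
on, plus complete truth tables:

* **Families** (`simulate_family`): one random ancestor per family
  (LTR–INT–LTR, identical LTRs); each copy draws an insertion age T and
  each of its two LTRs independently accumulates substitutions with
  per-site probability `r·T` (expected LTR–LTR divergence ≈ 2rT for small
  rT). A hotspot interval inside the LTR — standing in for the
  palindrome-rich, rapidly evolving regulatory region — mutates at an
  elevated multiple of the clock rate. The model is substitution-only:
  no indels, so family alignments are positionally trivial by
  construction, which is what lets exemplar building and LTR divergence
  avoid a multiple-sequence-alignment dependency.
* **Genomes** (`assemble_genome`): copies are placed without overlap on an
  i.i.d. random background. With probability `nesting_rate` an element
  receives a fragment of a different family (log-normal length, median
  189 nt — the scale reported for real nested fragments). The fragment
  *replaces* the host sequence at the insertion site rather than
  lengthening it: this keeps all copies of a family equal-length (the
  substitution-only premise) while still planting foreign sequence for
  the contamination and cross-talk analyses. A GFF3 annotation with
  LTR5/INT/LTR3 sub-features and a truth table are emitted alongside.
* **Exemplars** (`build_exemplar`): column-wise majority consensus;
  columns whose majority-base frequency falls below the mask threshold
  become N, so the hypervariable hotspot comes out as a contiguous N run,
  as in real exemplar databases.
* **Libraries** (`simulate_srna_library`): per element and read length,
  the number of species is Poisson with mean
  `base_rate × length × exp(−decay × T)` — young elements are silenced
  hardest and produce the most sRNAs, the empirical pattern the age
  analyses probe. Start positions overlapping the hotspot are up-weighted;
  strands are symmetric; every species is a perfect substring of its
  element; read counts follow a heavy-tailed geometric law
  (mean 5) with rare high-expression outliers so the dominance diagnostic
  has realistic material. The empirical expression distribution of real
  libraries is unknown to us; this law is a stand-in and no parameter of
  it is claimed to match maize.

### Standard study conditions

`synthetic_bundle()` pins the conditions used by the test suite and the
acceptance script: 200 elements in three families (90/70/40 copies),
300 nt LTRs with a 60 nt hotspot, 600 nt INT, ages uniform on 0.5–3 My,
r = 1.3e-8, genome background 60 kb, and the default silencing model
(24 nt-dominated, decay 1e-6/year).

Two parameters deserve an explicit derivation. With hotspot mutation at
5× the clock and My-scale ages, the per-site hotspot substitution
probability is only ~0.03–0.2, so every consensus column retains a
majority-base frequency far above 0.6 — a 5×-hotspot/0.6-threshold
combination can never produce N columns at these ages, whatever sample
size. The bundle therefore uses hotspot factor 25 and mask threshold
0.9: at ages 0.5–3 My the hotspot per-site probability is 0.16–0.75,
putting hotspot column majorities near 0.64 (far below 0.9) while
non-hotspot columns stay near 0.985 (far above it). The result is
deterministic, full-width N runs over the hotspot and none outside —
exactly the structure the exemplar analyses need. Both knobs remain
user-settable (`build_exemplar` keeps 0.6 as its permissive default for
generic consensus building).

## Numerical and design choices

* **Coordinates** are 0-based half-open everywhere internally; GFF3
  (1-based inclusive) and SAM (1-based) are converted at I/O boundaries
  only.
* **Exact matching** over A/C/G/T only: windows containing N are not
  indexed and species containing N never map, mirroring the implicit
  behaviour of zero-mismatch alignment. Reverse-complement palindromic
  species get both a sense and an antisense hit at the same position (two
  distinct locations); published location counts do not state their
  convention, so ours is explicit and tested.
* **Blocklist filtering** (miRNA/tRNA/rRNA/snoRNA) is exact full-sequence
  matching on either strand.
* **Alignment** uses Needleman–Wunsch with affine gaps (match +1,
  mismatch −1, a gap of length g costs 4 + g); ties between co-optimal
  alignments do not affect divergence because only aligned non-gap
  columns enter K.
* **Spearman p-values** use the t approximation
  `t = r sqrt((n−2)/(1−r²))`; an exact permutation p is available for
  n ≤ 8 (full enumeration; larger n would need 10!+ permutations for a
  convenience option and the t approximation is already adequate there).
* **The zoning split** maximises between-group variance on log10 total
  expression (a 1-D Otsu threshold); the flag requires the upper/lower
  median ratio to exceed the factor (default 1.5) before, and fall below
  it after, removal of the globally top-expressed species. A degenerate
  split (all totals equal) is treated as ratio 1.
* **Problem sizes**: the suite validates the mapper against a quadratic
  window-scan oracle on 1,000 species vs 10 kb of reference, age recovery
  on 500 elements with 1 kb LTRs (observed JC69 bias ≈ 1–2%, well inside
  the 5% claim), and the direction-of-effect suite on three seeds of the
  200-element bundle. These sizes were chosen so the whole suite runs in
  a couple of minutes while every estimate has comfortable statistical
  margin.

## What passing tests do and do not show

One interaction is worth flagging: because the bundle's hotspot mutates
much faster than the clock, whole-LTR divergence over-estimates the
insertion age of bundle elements (the hotspot contributes excess
substitutions). This mirrors a real caveat of whole-LTR dating in
families with hypervariable regulatory regions; clock-calibration tests
therefore use families simulated with the hotspot factor at 1.

The generator reproduces multi-mapping structure, age-dependent sRNA
production, hotspot hypervariability, exemplar masking and nested
contamination — the features the method's conclusions rest on. It does
not emulate real base composition, indels, solo-LTR formation,
transposition bursts, library-construction biases, or between-library
normalisation (all comparisons are within-library by design). Direction
tests on synthetic data therefore demonstrate that the machinery detects
these effects when present with the expected sign — not that any
particular magnitude will be observed in a real genome.
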