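Package: tesmap
Title: Mapping and Quantification of Small RNA Libraries on Transposable
    Element References
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact, zero-mismatch, all-hits mapping of small-RNA (and mRNA)
    sequence species against genomes, annotated transposable-element (TE)
    populations and TE exemplar consensuses, with unique/multi-mapper
    classification, 1/x location weighting, per-nucleotide species and
    expression densities, strand-resolved windowed profiles, family
    cross-talk statistics, foreign-fragment (contamination) screening, and
    LTR-divergence insertion-age estimation for LTR retrotransposons. A
    synthetic genome and small-RNA library simulator with full truth tables
    supports desk-scale validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
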