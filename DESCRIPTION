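Package: cytoniche
Title: Climatic Niche Comparison and Ploidy-Aware Variant Filtering for
    Cytotype Delimitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational evidence chain used to delimit
    cytotypes (e.g. a diploid segregate of a tetraploid species) as
    distinct species: great-circle deduplication of occurrence records,
    extraction and pruning of bioclimatic predictors, principal component
    niche space, kernel-density niche models with Schoener's D overlap,
    standardized Levins' B breadth and permutation inference, morphometric
    group comparisons with a determination-key classifier, and a
    ploidy-aware VCF filter cascade (depth window, genic/TE exclusion,
    singleton removal, linkage thinning) feeding fragment-based species
    tree inputs and ploidy-aware Dxy. A seeded synthetic-data module
    generates occurrences, environmental rasters, trait tables and
    mixed-ploidy variant matrices with known ground truth so the whole
    pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
RoxygenNote: 7.3.3
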