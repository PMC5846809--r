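Package: hemicnv
Title: Rare Copy-Number Variant Prioritization and Burden Analysis for Trio Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing copy-number variants (CNVs) detected in
    proband-parent trios and for case-control burden analysis. Implements
    reciprocal-overlap interval algebra, rarity filtering against a large
    population control panel, restriction to copy-number-stable regions,
    trio-based inheritance classification (de novo, maternal, paternal),
    clinical tiering against genomic-disorder loci and disease-gene lists,
    per-individual pLI (loss-of-function intolerance) deletion burden,
    brain-region by developmental-timepoint critical-exon carrier burden
    with Benjamini-Hochberg correction, and cohort stratification
    statistics. Includes a fully labeled synthetic cohort generator so
    every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
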