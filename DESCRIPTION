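Package: pipseqr
Title: Nuclear Protein Interaction Profile Sequencing (PIP-seq) Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for nuclear PIP-seq experiments: per-nucleotide
    RNA secondary-structure scores from paired dsRNase/ssRNase libraries,
    protein-protected site (PPS) calling by Poisson enrichment with a
    label-swap permutation false discovery rate, condition-specific interval
    classification, metagene and peak-centered profiles of structure, RNA
    binding protein occupancy and m6A density, and integrative statistics
    linking structure changes to transcript stability (proportion uncapped),
    abundance and protein output. Includes a deterministic synthetic-data
    generator with planted ground truth so every stage is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0), jsonlite, withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
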