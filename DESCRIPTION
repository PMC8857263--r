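Package: liquidbiopsy
Title: Copy-Number Profiling and Analytics for Liquid-Biopsy CTCs and cfDNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comprehensive liquid-biopsy analysis of circulating
    tumor cells (CTCs) and cell-free DNA (cfDNA) from binned read counts:
    median normalization and circular binary segmentation of genome-wide
    copy-number profiles, a hyperbolic-tangent genomic-instability (GI)
    score with neutral/aberrant bands, gain/loss alteration calling at
    fixed copy-ratio limits, clone detection from shared alterations,
    CTC-referenced estimation of the tumor-derived fraction of cfDNA,
    and cellular analytics (CTCs/ml enumeration, kinetics classification,
    SDOM morphometry, longitudinal variant-allele-frequency trajectories).
    A synthetic-data module generates clone-structured genomes, negative-
    binomial bin counts, slide cell tables and longitudinal draw series so
    every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
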