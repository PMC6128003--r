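Package: rlkfam
Title: Genome-Wide Identification and Characterization of LRR-RLK Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested, reusable pipeline for genome-wide analysis of the
    leucine-rich-repeat receptor-like kinase (LRR-RLK) gene family:
    similarity-based candidate screening with an internal seeded
    Smith-Waterman search, a three-evidence membership rule (LRR repeat,
    kinase domain, transmembrane helix), reference-anchored neighbor-joining
    phylogeny with p-distances and bootstrap supports, subclade assignment,
    chromosomal distribution and tandem-duplication-event calling,
    protein physicochemical characterization (pI, molecular weight, LRR
    consensus scanning, hydropathy-based transmembrane prediction),
    RPKM expression profiling with hierarchical clustering, qPCR ddCt
    analysis, and salt-stress physiology calculations (chlorophyll content,
    electrolyte leakage). A seeded synthetic-data generator with planted
    ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
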