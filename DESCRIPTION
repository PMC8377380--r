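Package: dsnfuse
Title: Multi-Property Drug Similarity Network Fusion for Drug Repositioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds per-property drug similarity networks from clinical
    (side-effect profiles), chemical (atom-pair fingerprints) and
    pharmacological (protein-target sequence) data, fuses them non-linearly by
    similarity network fusion, and mines the integrated network for drug
    repositioning: spectral clustering with validity-index model selection,
    ATC-based partition evaluation (NMI, overlap rates, Rogers-Tanimoto),
    per-edge data-type attribution, hypergeometric cluster enrichment,
    high-similarity pair and unexpected-drug candidate extraction, and a
    synthetic drug-universe simulator with planted cluster structure for
    end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    cluster,
    ChemmineR,
    ChemmineOB,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
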