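Package: growthnet
Title: Gene Co-Association Networks from Multi-Trait GWAS via AWM and PCIT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns multi-trait genome-wide association results into gene-gene
    co-association networks. Implements pedigree-based mixed-model association
    (numerator relationship matrix, REML variance components, likelihood-ratio
    tests), the Association Weight Matrix (AWM) selection cascade over key and
    supportive phenotypes, the PCIT (partial correlation and information theory)
    edge-significance algorithm, permutation-based network validation, MCODE
    dense-cluster detection, and binomial over-representation tests. Includes a
    gene-drop simulator for F2 crosses with planted pleiotropic gene modules so
    the whole pipeline can be exercised with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
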