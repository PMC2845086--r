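Package: crossgsea
Title: Cross-Tissue Gene Set Enrichment Analysis of Leukemia Transcriptional Programs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for comparing transcriptional programs across
    expression datasets. Builds directed (up/down) gene signatures from a
    reference expression panel by one-vs-rest Welch t-statistics with FDR
    truncation, then tests their enrichment in the genetic subtypes of a
    second dataset using a from-scratch Kolmogorov-Smirnov running-sum gene
    set enrichment analysis with phenotype permutations, normalized
    enrichment scores and permutation-based FDR. Includes readers/writers
    for GCT, CLS and GMT formats, the standard microarray preprocessing
    chain (floor, mean-centering, variation filter, probe collapse), and a
    synthetic-data generator that plants partially overlapping expression
    modules in linked datasets so every stage is testable without external
    accessions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
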