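Package: aopfinger
Title: Adverse Outcome Pathway Fingerprinting and Biomarker Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for linking adverse outcome pathways (AOPs)
    to toxicogenomic data. Provides text-based annotation of key events (KEs)
    to gene-set terms using IDF-weighted Jaccard matching, Fisher-exact
    gene-set enrichment with an AOP "fingerprint" decision rule, similarity
    based grouping of KEs and AOP network merging, network-centrality and
    specificity-driven biomarker prioritization with Borda rank aggregation,
    benchmark-dose (BMD) modeling with AIC model selection and
    profile-likelihood confidence bounds, and comparative-Ct qPCR validation
    statistics. Deterministic synthetic-data generators emulate every input
    shape with planted signal so each stage can be exercised and benchmarked
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
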