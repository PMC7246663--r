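Package: ComorbidNet
Title: Comorbidity Network Analysis of ICD-10 Diagnosis Records
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and analysis of disease comorbidity networks from
    patient-level ICD-10 diagnosis records. Provides index-disease cohort
    construction from long or wide delimited files, stratified prevalence
    and comorbidity-count statistics with chi-squared/Fisher group
    comparisons, pairwise relative risk against an independence expectation,
    thresholded weighted network assembly with GEXF/GraphML/edge-list export,
    weighted-modularity (Louvain) community detection with an exact
    small-graph partition oracle, and a planted-module synthetic cohort
    generator with closed-form expected statistics for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    xml2,
    jsonlite,
    S4Vectors,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
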