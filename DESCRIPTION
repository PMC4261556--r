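Package: gcnet
Title: Case-Control Gene Coexpression Network Analysis for Transcriptome Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and compares hard-threshold Pearson gene coexpression
    networks between a disease group and controls from one-color microarray
    intensity data. Provides spot-flag filtering, intensity-dependent
    (lowess) normalization against a virtual reference array, differential
    expression selection by the exact Wilcoxon-Mann-Whitney test or by
    Significance Analysis of Microarrays (SAM) with permutation-based FDR,
    hard-threshold network construction with hub ranking and module
    detection, and a condition-versus-control comparison report of common
    hubs and network topology. Includes a synthetic-data generator with
    planted correlation modules, hub genes and differential expression for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    xml2
Config/testthat/edition: 3
biocViews: GeneExpression, Network, Microarray, DifferentialExpression,
    GraphAndNetwork, Transcriptomics
RoxygenNote: 7.3.3
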