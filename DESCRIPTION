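Package: SNet
Title: Phenotype-Specific Pathway Subnetwork Discovery from Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies connected subnetworks of curated pathways whose genes
    are consistently highly expressed in one phenotype of a two-or-more
    phenotype expression study. Genes are filtered by a per-patient top-rank
    cut and a cross-patient frequency threshold, segregated into connected
    components within each pathway, scored per patient by the within-phenotype
    support of their genes, and compared between phenotype groups with a
    t-statistic. Significance is assessed against a (size, score) null
    distribution built by permuting phenotype labels. Includes cross-dataset
    consistency metrics (gene-list and subnetwork overlap), a per-gene t-test
    baseline, a synthetic-data generator with planted differentially expressed
    components, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    optparse
Suggests:
    testthat (>= 3.0.0),
    igraph,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
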