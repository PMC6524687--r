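Package: pmena
Title: Phylogenetic Molecular Ecological Network Analysis of Microbiome OTU
    Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds signed co-occurrence networks from 16S OTU abundance
    tables using random-matrix-theory (RMT) thresholding of the absolute
    Pearson correlation matrix.  Provides the standard pre-network steps
    (rarefaction, prevalence filtering, relative-abundance conversion),
    nearest-neighbour eigenvalue-spacing analysis (Poisson versus Gaussian
    orthogonal ensemble statistics) to choose the similarity threshold,
    global network topology indices, greedy modularity-based module
    detection, within-module degree and participation-coefficient node role
    classification (peripherals, connectors, module hubs, network hubs),
    degree-preserving random-network null ensembles with Student t
    comparisons, and Spearman association of signed OTU degrees and keystone
    taxa with clinical tumour markers.  A synthetic-data generator with
    planted modular signed correlation structure makes every stage testable
    without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
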