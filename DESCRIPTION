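Package: seqclass
Title: Sequence Classes: A Regulatory Vocabulary from Chromatin-Profile
    Sequence Models
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to learn a vocabulary of regulatory activities
    ("sequence classes") from DNA sequence alone.  A convolutional
    sequence model with dual linear/nonlinear paths, residual dilated
    convolutions and a B-spline spatial basis predicts chromatin-profile
    peak probabilities at the center of fixed-length windows; genome-wide
    predictions are reduced with incremental PCA, clustered with Louvain
    community detection on a k-nearest-neighbor graph, and summarized as
    unit class vectors.  Projection of predictions onto class vectors
    yields sequence-class scores and directional variant effects (with
    nucleosome-occupancy normalization of histone-mark predictions), and
    downstream population-genetics statistics: annotation enrichment,
    tissue-expression and eQTL correlations, allele-frequency constraint
    z-scores, and construction of nonoverlapping heritability-partitioning
    annotations.  A synthetic-cohort generator makes every stage testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    splines,
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
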