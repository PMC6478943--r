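Package: AirwaySubtypes
Title: Molecular Subtyping of Bronchial Premalignant Lesions from
    Multi-Cohort Expression Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end workflow for discovering and classifying
    molecular subtypes of bronchial premalignant lesions from bulk
    RNA-seq expression data. Implements cross-dataset co-expression
    module detection and conservation screening, consensus clustering
    with CDF-area selection of the number of subtypes, a compact
    nearest-centroid subtype classifier with inverse-proportional
    marker allocation, single-sample gene-set activity scoring, and
    repeated-measures association of module scores with lesion
    progression. Ships a factor-model simulator that generates linked
    multi-dataset expression studies with planted modules, subtypes
    and progression labels for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    edgeR,
    sva,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    statmod,
    fgsea
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, Clustering, Classification,
    RNASeq
RoxygenNote: 7.3.3
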