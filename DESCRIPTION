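Package: CoFracPPI
Title: Protein Complex Inference from Co-Fractionation Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers protein-protein interactions and multi-protein complexes
    from co-fractionation mass spectrometry (CoFrac-MS) elution profiles.
    Provides spectral-count profile import, filtering, normalisation and
    smoothing; size-exclusion chromatography mass calibration with apparent
    mass (Mapp) and oligomerisation-state (Rapp) calling; five co-elution
    features (Pearson, Jaccard, Apex, mutual information, Bayes correlation)
    for candidate protein pairs; gold-standard-trained random-forest
    classification of co-complex membership with complex-level
    cross-validation; cohesiveness-based graph clustering of the scored
    interaction network into complexes; post-inference network statistics;
    and a synthetic fractionation-data generator with planted complexes for
    end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    BiocGenerics,
    randomForest,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
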