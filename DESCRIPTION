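Package: CorticalScore
Title: Score-Matrix Classification and Continuous Severity Staging from
    Cortical Thickness
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Classifies brain MR images into cognitively normal (CN), mild
    cognitive impairment (MCI) and Alzheimer's disease (AD) cohorts from
    vertex-wise cortical-thickness profiles, and assigns every image a
    continuous severity degree on a 0 (CN basin) to 1 (AD basin) scale.
    Images are partitioned into groups by mean cortical thickness,
    discriminative region-of-interest vertices are selected by pairwise
    Welch Z scores, per-cohort probability and negative-log-probability
    score matrices are built over 0.2 mm thickness bins with a discrete
    nine-point smoothing kernel, and the severity degree is derived from a
    max-normalized covariance correlation matrix of standardized thickness
    profiles. Includes a synthetic cohort simulator with planted effect
    vertices and latent severity, stratified k-fold cross-validation,
    singular-value-decomposition model diagnostics, and a small pipeline
    runner. Containers build on SummarizedExperiment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'thickness-io.R'
    'grouping.R'
    'roi.R'
    'score-model.R'
    'severity.R'
    'svd.R'
    'validation.R'
    'simulate.R'
    'pipeline.R'
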