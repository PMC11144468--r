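Package: scoreMR
Title: Drug-Target Genetic Score Association and Meta-Analysis Pipeline
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructs weighted drug-target locus genetic scores calibrated
    to standard-deviation units of LDL cholesterol, with block-jackknifed
    internal weights that remove weak-instrument bias, and tests their
    associations with continuous biomarkers and binary disease endpoints by
    region-stratified regression pooled with inverse-variance-weighted
    fixed-effect meta-analysis. Includes summary-statistic operators
    (confidence-interval back-calculation, Wald tests, per-allele rescaling,
    Cochran's Q heterogeneity, Benjamini-Hochberg and Bonferroni control),
    LMS lower-limit-of-normal spirometry classification of chronic
    obstructive pulmonary disease, ICD-10 endpoint construction with
    control-exclusion rules, a phenome-wide scan, and a synthetic biobank
    cohort generator for validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'simulationConfig.R'
    'simulateCohort.R'
    'transform.R'
    'meta.R'
    'score.R'
    'association.R'
    'respiratory.R'
    'io.R'
    'pipeline.R'
    'publishedEstimates.R'
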