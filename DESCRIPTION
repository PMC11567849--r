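Package: txnimage
Title: Transcription-Neuroimaging Association Analysis for Seed-Based
    Connectivity Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline linking intervention-induced changes in
    seed-based functional connectivity to spatial brain gene expression,
    behavioral composites, and protein-protein interaction network
    structure. Computes per-subject Fisher-z seed-connectivity maps from
    4D BOLD arrays, voxelwise 2x2 mixed (group x timepoint) ANOVA with
    Monte-Carlo cluster-extent family-wise-error correction, PCA-based
    sleep-quality grouping and covariate-adjusted behavioral correlations,
    gene-wise cross-sample correlation against regional connectivity
    change with Benjamini-Hochberg selection and a variogram-matched
    (spatially constrained) permutation null, and degree-based hub-gene
    analysis of STRING-dialect interaction networks. Includes synthetic
    generators for cohort scans, spatially autocorrelated expression
    samples, and background interaction graphs so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
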