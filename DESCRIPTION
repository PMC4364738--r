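Package: fcnet
Title: Weighted Functional Connectome Construction, Efficiency Metrics and
    Group Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds sparse positive weighted brain networks from regional
    BOLD time series (Pearson correlation with Bonferroni significance
    thresholding), computes global, local and nodal efficiency with
    degree-preserving null-model normalization, detects modules by spectral
    modularity optimization, and performs permutation-based group inference
    with FDR control, module-enrichment resampling and partial correlations
    against clinical covariates. Includes a factor-model synthetic-cohort
    generator with planted modular structure, group effects, motion
    confounds and covariate coupling, so the full pipeline is testable
    without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
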