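Package: metaprog
Title: Supervised Metagene Discovery and Proliferation-Conditional
    Survival Analysis
Version: 0.1.0
Authors@R:
    person("Metaprog", "Developers", email = "metaprog@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering survival-associated gene subclusters in
    bulk tumor expression cohorts and quantifying their conditional
    prognostic effects.  Provides covariate-balanced cohort randomization
    monitored by standardized differences, genome-wide per-probe Cox
    proportional-hazards screening with false-discovery-rate control,
    average-linkage hierarchical clustering with nested-branch subcluster
    extraction at an average-correlation threshold, metagene construction
    with probe-to-gene collapsing and tertile stratification, nearest
    centroid intrinsic subtype classification, proliferation-tertile
    conditional survival analyses including multivariable Cox models and
    combinatorial immune-tertile profiles, and a synthetic multi-study
    cohort generator with planted proliferation and immune latent factors
    for validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    optparse,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
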