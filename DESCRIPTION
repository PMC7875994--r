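Package: patchval
Title: Patch-Leaving and Value-Guided Choice: Task Simulation,
    Behavioural Modelling and Cortical E/I Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Generative simulator for a two-stage foraging task combining
    patch-leaving decisions with value-guided choices, using decaying
    Gaussian random-walk patch dynamics. Implements a family of subjective-
    value choice models with prospect-theoretic probability weighting and
    utility curvature, constrained multi-start maximum-likelihood fitting,
    BIC model comparison and parameter recovery. Provides per-participant
    behavioural statistics (patch-leaving advantage, cost-dependent leave
    thresholds, repeated-measures ANOVA with linear trend, z-scored
    trial-level regressions with group-level tests), metabolite
    normalization for MRS voxel measurements, and a gated hierarchical
    analysis relating regional excitation/inhibition ratios to individual
    decision variables. Includes a synthetic cohort generator with planted
    individual-difference effects for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
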