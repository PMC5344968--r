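Package: seedshadow
Title: Inverse Estimation of Seed Dispersal Kernels and Seed-to-Seedling
    Recruitment from Mapped Stands and Seed Traps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits parametric two-dimensional seed dispersal kernels
    (power-exponential and 2Dt) to seed-trap counts collected in mapped
    conspecific stands, using a hierarchical Bayesian negative-binomial
    observation model with lognormal site-level fecundity effects, MCMC
    sampling, Gelman-Rubin convergence diagnostics and DIC model
    comparison across island-level hypotheses about kernel scale.
    Companion binomial GLM/GLMM stages model frugivore ingestion of
    seeds, germination by fruit-handling treatment, and
    distance-dependent (Janzen-Connell) seedling survival, with AICc
    selection and profile-likelihood intervals. An integrative metric
    composes all stages into overall seed-to-seedling survival under
    frugivore-present and frugivore-absent scenarios, with Monte-Carlo
    propagation of kernel and regression uncertainty. A synthetic-data
    generator emulates the field designs (wedge-shaped 17-trap arrays,
    nursery germination trials, near/far outplanting and seed-addition
    plots) with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
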