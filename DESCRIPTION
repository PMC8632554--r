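Package: coxfc
Title: Seed-Based Functional Connectivity Survival Modelling for Relapse
    Prognosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise Cox proportional-hazards modelling of seed-based
    resting-state functional connectivity against censored time-to-relapse
    outcomes. Provides a self-contained partial-likelihood engine
    (Newton-Raphson, Breslow or Efron ties), Kaplan-Meier estimation,
    motion-based quality control and time-series cleaning, Fisher-z seed
    connectivity maps, mass-univariate survival screening into protective
    and risk circuit masks, composite index construction, a final
    covariate-adjusted Cox model evaluated by fixed-cutoff ROC analysis
    under nested leave-one-out cross-validation with a permutation-based
    empirical null, post-hoc circuit-frequency heat maps and k-means
    disease subtyping, and a synthetic-cohort generator with planted
    circuits for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mclust,
    optparse,
    signal,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
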