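Package: phenonet
Title: Cross-Prediction Feature-Importance Networks for Deep Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deep phenotyping of mixed-type patient questionnaire cohorts by
    cross-prediction. Every feature is predicted from all non-trivially-related
    others with tuned gradient-boosted tree models; the per-target feature
    importances are assembled into a directed weighted network whose community
    structure is inferred with a nested weighted stochastic block model by
    minimum-description-length simulated annealing. Weighted eigenvector, hub
    and authority centralities per community quantify which feature domains act
    as hubs versus authorities and influencers. Includes a synthetic-cohort
    generator with planted cross-domain latent structure, missing-at-random
    masking and class imbalance, a preprocessing chain (missingness filters,
    chained-equation imputation with predictive mean matching, percentile
    clamping, train-fitted normalisation, minority oversampling), correlation
    cluster maps with false-discovery-rate control, and block-level contrasts
    by one-way ANOVA with Tukey honest significant differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    ape,
    xgboost,
    pROC,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
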