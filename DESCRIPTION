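Package: comorbnet
Title: Multimorbidity Pattern Analysis with Standardised Lift and
    Comorbidity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pattern analysis of multimorbidity in survey cohorts:
    survey-weighted prevalence estimation and per-condition sex-association
    testing with false-discovery-rate correction; association-rule mining of
    disease pairs and triads ranked by the standardised lift, an interest
    measure that rescales the lift (observed/expected ratio) onto [0,1] by
    its margin-dependent attainable bounds; co-occurrence network
    construction with fast-greedy modularity community detection; and a
    latent-Gaussian (Gaussian copula) simulator for correlated binary
    cohorts with known margins, calibrated planted dependence, sex strata
    and heterogeneous survey weights, so every stage of the analysis can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    mvtnorm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
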