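Package: erpmem
Title: Cluster-Based Permutation Tests and Recognition-Memory Indices for ERP Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for event-related-potential (ERP)
    studies of emotional memory under transcutaneous auricular vagus nerve
    stimulation (taVNS). Provides a synthetic-data generator for multi-sensor
    ERP epochs with known ground-truth effects and for trial-level recognition
    behavior from a dual-process (recollection/familiarity) generative model;
    the two-step spatiotemporal cluster-mass permutation test with max-statistic
    family-wise error control; signal-detection recognition indices (Pr, d-prime)
    with confidence-based recollection/familiarity splits; and random-intercept
    linear mixed models with Satterthwaite degrees of freedom and BIC-approximate
    Bayes factors. All tabular results are tibbles; fitted objects have
    broom-style tidy() and glance() methods and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    lme4,
    igraph,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
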