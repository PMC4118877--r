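Package: atam
Title: Ailment Topic Aspect Model for Health Topic Discovery in Short Texts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the ailment topic aspect model (ATAM), a probabilistic topic
    model for short self-reported health messages that assigns each document a
    latent ailment and each token a background, topic, or ailment role, with
    separate word distributions for general, symptom, and treatment aspects.
    Inference is by collapsed Gibbs sampling with interleaved Dirichlet
    hyperparameter optimization, informative word priors built from per-ailment
    reference articles, an incremental data schedule with sharded count
    pooling, an LDA-with-background baseline, a generative simulator for
    parameter-recovery studies, and utilities for temporal and geographic
    prevalence series and their correlation with external surveillance data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
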