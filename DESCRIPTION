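Package: moralinfer
Title: Computational Phenotyping of Moral Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation, model fitting, and group-level analysis for a
    moral inference task in which observers predict whether agents will
    trade pain inflicted on others for money. Implements a grid-based
    Bayesian learner over an agent's harm-aversion exchange rate whose
    effective learning rate scales dynamically with belief uncertainty,
    together with fixed-learning-rate comparison models, per-participant
    maximum-likelihood fitting with BIC-based model evidence,
    random-effects Bayesian model selection, a synthetic-cohort generator
    with group-specific learner profiles (untreated borderline personality
    disorder, matched controls, and therapeutic-community-treated
    patients), and the robust bisquare regression layer used to test
    agent-by-group differences in learning rates, impressions, and
    uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
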