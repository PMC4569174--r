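Package: carekit
Title: Male Care and Immature Fitness Proxies in Provisioned Macaque Groups
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for testing whether adult-male
    affiliation with immature group members predicts proxies of immature
    fitness (body-mass gain, body fat, testis volume) and whether
    parent-offspring co-residence predicts lifetime reproductive success
    in matrilineal primate societies. Provides daily Elo-based dominance
    ranks with matrilineal rank inheritance, five affiliation predictors
    including a Shannon-evenness partner distribution, growth-curve age
    normalization with AIC model selection, a Spearman correlation screen
    combined by permutation-calibrated Fisher omnibus tests,
    microsatellite paternity exclusion, a Poisson mixed model for
    lifetime reproductive success with full diagnostics, and a seeded
    synthetic-data generator emulating a free-ranging rhesus macaque
    population so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
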