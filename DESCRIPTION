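Package: metzones
Title: Environment Types and Adaptation Zones for Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of multi-environment trial networks into
    environment types with multi-layer self-organizing maps, and aggregation
    of trial locations into adaptation zones from environment-type
    frequencies.  Includes per-trial spatial mixed models with AR1xAR1
    residuals for adjusted genotype means (BLUEs), AMMI decomposition for
    biplot scores and genotype interaction weights, weighted-REML
    variance-component models for genotype-by-environment structure
    (including an unstructured genotype-by-zone covariance), factorial
    regression scanning of environmental covariables, leave-one-year-out
    cross-validation, correlated versus direct response to selection, and a
    synthetic trial-network simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
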