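Package: finfusion
Title: Phenotypic Assortment Tests and Fission-Fusion Group Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for asking whether males in fission-fusion animal
    societies are phenotypically assorted within mixed-sex social groups.
    Implements the pooled within-group variance (ANOVA mean square) as an
    assortment statistic with a membership-conserving Monte Carlo
    randomization test, an agent-based simulator of male movement among
    groups driven by a logistic rule on relative ornamentation, body size
    and group sex ratio, one-at-a-time sensitivity sweeps of the simulator
    with replicate trend regressions, and dichotomous-choice preference
    statistics (arcsine-square-root transform, one-sample and paired
    t-tests against chance, covariate regressions with type-II F-tests).
    A synthetic-data module generates phenotype tables, shoal structures
    and choice trials with the statistical structure these analyses
    assume, so the whole pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    MASS,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
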