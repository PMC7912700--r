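Package: canfa
Title: Entropy-Based Factor Contributions and Canonical Factor Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for interpreting fitted factor-analysis models through
    entropy. Given a loading matrix, a factor correlation matrix and unique
    variances, the package computes Kullback-Leibler signal-to-noise
    contributions of the common-factor vector to the manifest variables,
    decomposes them over variables, subgroups and canonical common factors,
    and derives interpretable (generally oblique) common factors from
    subgroups of manifest variables, re-expressing the loading matrix on the
    derived factors. Includes a synthetic factor-model generator, Monte-Carlo
    and sample-CCA oracles, plain-text model I/O and a small command-line
    interface. No raw data are required: all quantities are population
    functions of the fitted model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    MASS,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
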