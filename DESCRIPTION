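Package: signalrep
Title: Repertoire Construction, Dyadic Similarity and Mixed-Model Analysis of Non-Vocal Signal Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing per-act records of non-vocal communicative
    signals in immature great apes across wild and captive study populations:
    validation and profiling of interaction-record tables, construction of
    customary signal repertoires under eligibility (more than 30 interactions
    per partner scope) and customary-use (at least two uses) filters, dyadic
    Dice similarity matrices with label-permutation inference that respects
    row- and column-wise non-independence, Poisson generalized linear mixed
    models of repertoire size and social-goal diversity with likelihood-ratio
    inference and collinearity, dispersion and stability diagnostics, and a
    synthetic interaction-record generator with known ground truth for
    calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
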