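Package: ndcount
Title: Microbial Non-Detects as Raw Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical treatment of non-detects in microbial enumeration
    data as observed zero counts rather than left-censored measurements.
    Provides the probability of a non-detect under Poisson sampling with
    perfect, constant, or beta-distributed analytical recovery; the method
    sensitivity limit (MSL); gamma posteriors for concentration given a
    single count; most-probable-number estimation from presence/absence
    series; five estimators of lognormal concentration statistics in the
    presence of non-detects (omission, detection-limit substitution,
    half-limit substitution, left-censored lognormal MLE, and
    Poisson-lognormal MLE on raw counts); and a synthetic-data generator
    for simulation studies of non-detect handling bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    jsonlite
Config/testthat/edition: 3
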