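Package: txinit
Title: Rate-Limiting Steps of Transcription Initiation from Censored
    Single-Cell RNA Interval Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers the rate-limiting step structure of bacterial
    transcription initiation from intervals between consecutive RNA
    production events observed in single cells. Represents the on/off
    (telegraph) promoter model combined with up to three sequential
    initiation steps as a phase-type distribution, fits it to
    grid- and right-censored interval data by maximum likelihood,
    selects step structures by BIC with censored-sample weighting and a
    worst-case Delta-BIC lower bound, fits polynomial inverse-rate
    temperature laws jointly across conditions (including a shared
    shape-up-to-scale variant and an RNA-polymerase-abundance
    constrained variant), assesses fit by parametric bootstrap, and
    splits the mean interval into pre- and post-commit durations via
    Lineweaver-Burk extrapolation. Includes a synthetic-data generator
    reproducing the time-lapse microscopy observation design (sampling
    grid, finite movies, per-cell windows).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    MASS,
    pracma,
    lhs,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
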