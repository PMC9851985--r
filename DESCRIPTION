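Package: saradyn
Title: Temporal Dynamics of Ordinal Ataxia Rating Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models the longitudinal progression of ordinal clinical rating
    scales, with the Scale for the Assessment and Rating of Ataxia (SARA) in
    spinocerebellar ataxia as the motivating application.  Provides a
    generative ordinal disease-course model in which population-level
    durations (the average years spent at each score level) are combined with
    two individual parameters, a log acceleration factor and a
    start-of-progression age; MCMC-SAEM estimation with Geweke convergence
    diagnostics; posterior analyses of linearity, item speed and variability,
    genotype group dynamics and CAG-repeat/onset correlation; SARA to f-SARA
    score mapping and Cronbach alpha reliability with bootstrap intervals;
    two-arm trial sample-size and Monte-Carlo power computation; and a
    synthetic cohort generator emulating the structure of pooled natural
    history cohorts so the whole pipeline can be exercised without access to
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
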