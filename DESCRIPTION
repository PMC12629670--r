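Package: predseq
Title: Quantifying Antipredator Defense Effectiveness Along the Predation
    Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for aviary predation experiments in which wild
    insectivorous birds are presented with butterfly prey differing in
    antipredator defense (crypsis, aposematism, evasive flight). Codes
    timestamped behavioral events into predation-sequence outcomes, computes a
    two-stratum vertical co-occurrence index as a proxy for encounter chance,
    and compares five binomial partition hypotheses per predation stage with a
    base-10 log-likelihood, small-sample AICc and Akaike weights. Includes a
    stochastic trial simulator for testing and parameter-recovery studies, and
    self-contained nonparametric utilities (exact paired signed-rank test,
    Bonferroni adjustment, compact letter display).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
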