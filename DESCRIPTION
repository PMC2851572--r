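Package: teclines
Title: Detecting Climate-Adaptive Transposable-Element Insertions from
    Population Frequency Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring which transposable-element (TE) insertions
    in Drosophila melanogaster populations are adaptive to temperate
    climates.  Provides maximum-likelihood estimation of TE insertion
    frequencies from strain genotype calls under Hardy-Weinberg
    proportions, a likelihood-ratio test of frequency heterogeneity
    between population pairs, a mutation-selection-balance likelihood for
    family-level selection coefficients with single-strain ascertainment
    and a pooled-PCR misclassification observation model, candidate
    screening with false-discovery-rate correction and directionality
    summaries, latitudinal cline regression on angular-transformed
    frequencies, and a synthetic-data generator so that every stage of
    the pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
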