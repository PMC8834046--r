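Package: ginscore
Title: Gene-Expression Surrogate of Genomic Instability for Oral Carcinogenesis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives and applies a transcriptomic surrogate of genomic
    instability for squamous-cell carcinoma and oral potentially malignant
    disorders. Computes the fraction of genome altered (FGA) from segmented
    copy-number profiles, derives a gene signature by intersecting
    expression-FGA Pearson correlations across two cohorts, scores samples
    with a single-sample gene-set enrichment statistic (the GIN score), and
    relates the score to group labels and time-to-cancer outcomes via
    maximally selected log-rank cutpoints, Kaplan-Meier estimates and Cox
    proportional-hazards models. Includes a synthetic-cohort generator that
    plants known FGA-coupled genes and score-dependent hazards so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
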