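Package: allomplast
Title: Allometric Analysis of Organ-Specific Nutritional Plasticity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies how strongly individual organs respond to
    developmental nutrition by treating the allometric coefficient -- the
    slope of the log-log scaling relationship between organ and body size --
    as a measure of nutritional plasticity.  Provides standardized major
    axis (SMA) line fitting with correlation-based confidence intervals,
    likelihood-ratio and permutation tests for slope homogeneity between
    groups, anchor-point translation/rotation normalization of scaling
    relationships across rearing conditions, a permutation test for trends
    in SMA slope along a covariate such as temperature, proliferation-rate
    statistics for mitotic cell clones nested within larvae, and seeded
    synthetic-data generators so every stage of the pipeline can be
    validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
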