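Package: tricall
Title: Tri-Class Pathogenicity Prediction for Amino Acid Substitutions
    with a Reject Option
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies amino acid substitutions as pathogenic, neutral or
    unknown using an ensemble of random forests trained on stratified
    bootstrap resamples.  Per-variant features combine evolutionary
    conservation (codon-level Ka/Ks selective pressure and multiple
    sequence alignment profiles), physicochemical amino acid properties
    from AAindex, a Gene Ontology log-ratio feature, and class priors from
    functional-site annotations merged by a noisy-OR rule.  Predictions
    whose distribution-free (Chebyshev) reliability interval around the
    mean bootstrap probability contains 0.5 are rejected as unknown.
    Includes family-aware two-step greedy feature selection, a six-metric
    evaluation suite with the normalized Matthews correlation coefficient
    and the performance-cuboid overall performance measure, and a
    synthetic data generator so the whole pipeline is testable without
    external resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
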