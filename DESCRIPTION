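Package: ecotoxeval
Title: Evaluation of In Silico Acute Aquatic Toxicity Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to benchmark in silico predictions of acute aquatic
    toxicity (daphnia 48-h and fish 96-h LC50) against experimental data.
    Implements GHS acute category classification, qualitative and
    quantitative accuracy metrics (total accuracy, predictive power,
    fold-factor accuracy, RMSE and R-squared on the log10 scale, error
    distributions), applicability-domain-conditioned scoring, per-tool
    prediction consolidation rules including an integrated multi-model
    selection strategy, a read-across and trend-analysis category engine
    driven by log Kow and organic functional groups, a water-solubility
    plausibility screen, and seeded synthetic-data generators so the whole
    pipeline is testable without external software. Ships a benchmark
    dataset of 37 priority controlled chemicals with predictions from seven
    tools as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
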