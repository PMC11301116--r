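Package: nmbtrends
Title: Neuromuscular Blockade Reversal Trend and Counterfactual Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the choice of neuromuscular blockade (NMB)
    reversal strategy (sugammadex, neostigmine, or spontaneous recovery) in US
    adult inpatient surgery evolved across pre-pandemic and COVID-19 eras.
    Provides a synthetic encounter-level generator emulating a large hospital
    discharge database, cohort inclusion/exclusion and deduplication rules,
    stratified descriptive tables and quarterly trend series, multivariable
    logistic trend models with era-by-trend interaction terms, and a
    counterfactual framework that extrapolates a pre-pandemic model into the
    pandemic eras, calibrates a classification cutoff to observed class
    counts, and reports normalized actual-versus-counterfactual odds ratios
    with Woolf confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    pROC,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
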