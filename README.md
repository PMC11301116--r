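# nmbtrends

Trend and counterfactual analysis of neuromuscular blockade (NMB) reversal
choice in US adult inpatient surgery across the COVID-19 eras.

After surgery under rocuronium or vecuronium, neuromuscular function is
restored spontaneously or reversed actively with neostigmine or
sugammadex. Sugammadex use has risen steadily since 2016, and the pandemic
could plausibly have disturbed that trend. `nmbtrends` is for
pharmacoepidemiologists and biostatisticians who want a tested, reusable
implementation of the full analysis chain on encounter-level data:

* **synthetic cohorts** — a generator emulating a large all-payer hospital
  discharge database (covariate margins, two-stage logistic reversal
  outcome, exclusion markers, 30-day repeat surgeries), so everything is
  testable without proprietary data;
* **cohort construction** — inclusion/exclusion rules with an exactly
  reconciling attrition report, rolling 30-day first-surgery
  deduplication, era assignment (BP/BC/EC/MC/LC with a March-2020
  washout), reversal and NMB-group classification;
* **descriptives** — stratified count/percentage tables by era and
  quarterly reversal-share series with OLS linearity (R²);
* **trend models** — multivariable logistic regression of reversal choice
  with a continuous yearly trend *t* and era-by-trend interactions:

  logit P(outcome) = β₀ + β_t·t + Σ_e γ_e·t·1_era(e) + β'x

  model 1a contrasts active vs spontaneous reversal, model 1b sugammadex
  vs neostigmine; exp(β_t) is the yearly trend OR, exp(γ_e) the
  acceleration of that trend within era e;
* **counterfactual framework** — a pre-pandemic model (2018-01 to 2020-02,
  trend included, no interactions) extrapolated to pandemic-era patients,
  classification cutoff calibrated by rank so predicted class counts
  equal observed counts exactly, and per-covariate actual-vs-counterfactual
  odds ratios with Woolf CIs, normalized so the patient-weighted OR is 1.

## Worked example

```r
library(nmbtrends)

enc <- generate_encounters(synthetic_config(n_encounters = 100000, seed = 1))
built <- build_cohort(enc)
built$report
#> <nmb_filter_report>
#>   input: 100000   retained: 92463
#>   removed:
#>     myasthenia_gravis  170
#>     renal_failure      2988
#>     pyridostigmine     91
#>     dual_reversal      385
#>     obstetric          1865
#>     covid_dx           431
#>     washout            1607
#>   retained per era: BP=39153 BC=19432 EC=6422 MC=8128 LC=19328

fit <- fit_trend_model(built$cohort, model_spec("sugammadex_vs_neostigmine"))
report_fit(fit)[1:4, c("term", "or_ci", "p_value")]
#> # A tibble: 4 × 3
#>   term     or_ci                p_value
#>   <chr>    <chr>                  <dbl>
#> 1 t        1.392 (1.342-1.445) 1.26e-68
#> 2 t:era_EC 1.033 (0.999-1.067) 5.66e- 2
#> 3 t:era_MC 0.990 (0.960-1.020) 4.99e- 1
#> 4 t:era_LC 0.998 (0.970-1.026) 8.81e- 1
```

The trend row says sugammadex's odds relative to neostigmine grew about
1.39-fold per year in this cohort (the generative value is 1.388); the
interaction rows say none of the pandemic eras significantly changed that
slope at this sample size, matching the generative shocks of 1.008, 0.992
and 1.001.

```r
cf <- run_counterfactual(built$cohort)
cf$model
#> <nmb_counterfactual_model> contrast 2b, n=30147, AUROC=0.624
subset(cf$table, covariate == "(all)")[, c("era", "n", "ratio", "normalized_ratio")]
#> # A tibble: 3 × 4
#>   era       n ratio normalized_ratio
#>   <chr> <int> <dbl>            <dbl>
#> 1 EC     4750 1.93                 1
#> 2 MC     6088 1.29                 1
#> 3 LC    14557 0.690                1
```

The per-era `(all)` ratios capture the drift of the extrapolated model;
normalization rescales each era so subgroup rows are read relative to it.
See the methods vignette for an important caveat about interpreting
subgroup normalized ratios from count-matched hard labels, and the
`label_method = "expected"` alternative.

An end-to-end run with artifacts (filter report, descriptive tables,
model reports, counterfactual table, manifest) is one call:

```r
run_pipeline(pipeline_config(
  input = synthetic_config(n_encounters = 100000),
  output_dir = "nmb-artifacts", seed = 1
))
```

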