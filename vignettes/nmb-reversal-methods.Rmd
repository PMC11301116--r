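---
title: "Modelling NMB reversal choice across the COVID-19 eras"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling NMB reversal choice across the COVID-19 eras}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmbtrends)
```

## The scientific question

After surgery under neuromuscular blockade (NMB) with rocuronium or
vecuronium, muscle function is restored either spontaneously or by active
pharmacologic reversal with neostigmine or sugammadex. Since sugammadex's
2016 US approval its use has grown steadily, and the COVID-19 pandemic —
with its pressure to shorten recovery-room stays and limit aerosol
exposure — could plausibly have accelerated or disturbed that trend.
`nmbtrends` implements an analysis pipeline for this question on
encounter-level inpatient surgery data: cohort construction, descriptive
trend statistics, interrupted-time-series logistic models with era
interactions, and a counterfactual framework that asks how pandemic-era
patients *would* have been reversed under pre-pandemic practice.

Because the kind of all-payer hospital discharge database such analyses run
on is proprietary, the package ships a synthetic encounter generator whose
defaults emulate the structure of a US inpatient cohort of roughly 3.6
million procedures (2017-03-01 to 2021-12-31). Every downstream stage is
exercised and tested against that generator.

## Study eras and the time axis

Encounters are grouped into five eras: baseline (BP, 2017-03-01 to
2019-02-28), pre-COVID (BC, 2019-03-01 to 2020-02-29), early COVID (EC,
2020-04-01 to 2020-07-31), middle COVID (MC, 2020-08-01 to 2020-12-31) and
late COVID (LC, 2021). March 2020 is a washout month — a transition period
with unreliable COVID-19 diagnosis capture — and is excluded.

The continuous time covariate is

$$t = \frac{\text{date} - \text{2018-01-01}}{365.25},$$

fractional years since an anchor, so an exponentiated trend coefficient is
a *per-year* odds ratio. The anchor choice only moves a fitted model's
intercept: trend and interaction odds ratios are invariant (tested
numerically; exact invariance of interaction terms additionally requires
era main-effect columns, which `model_spec(include_era_main_effects =
TRUE)` provides). Models fit on encounters from 2018-01-01 onward, the
window in which the reversal shares evolve nearly linearly; descriptive
tables use the full study range.

## Cohort construction

`apply_filters()` retains adults (≥ 18 years) who received rocuronium or
vecuronium and removes: myasthenia gravis, renal failure, pyridostigmine
therapy, reversal with *both* active agents, obstetric procedures, COVID-19
diagnoses (applied to 2020–2021 encounters only), and washout or
out-of-study dates. Reasons are evaluated in that fixed order and each row
is counted under its first matching reason, so the attrition report
reconciles exactly — the order itself is a package convention, since
attrition order is rarely reported in source studies.

`deduplicate_first_surgery()` keeps, per patient, only surgeries at least
30 days after the previously kept one (a rolling window anchored at each
kept surgery). Inpatient-stay identifiers are not modelled; the date rule
governs. Filtering precedes deduplication in `build_cohort()`.

## The trend-interaction models

Two multivariable logistic regressions share one design:

* **model 1a** — active (sugammadex or neostigmine) vs spontaneous
  reversal, all encounters;
* **model 1b** — sugammadex vs neostigmine, actively reversed encounters
  only.

The linear predictor contains an intercept, the yearly trend $t$, one
$t \times \mathbf{1}_{\text{era}}$ interaction per pandemic era, and
dummy-coded covariates: NMB agent group, age band, sex, race, ethnicity,
admission type, low-income insurance, nine comorbidity flags, surgical
type, bed size, teaching status, region, and COVID-19 history
(`default_covariate_terms()` lists the reference levels). Era main effects
are *excluded* by default: the pandemic enters as a change in slope, not
level, which matches how such era effects are usually reported; a flag
restores them for sensitivity analysis.

A positive interaction coefficient for, say, EC in model 1b means the
likelihood of sugammadex use rose *faster* during early COVID than the
pre-pandemic trend predicts.

Fitting is maximum likelihood by iteratively reweighted least squares
(through `stats::glm.fit`, relative deviance tolerance $10^{-10}$, 100
iterations max) behind a full-rank check; Wald standard errors come from
the inverse observed information. Rank deficiency, non-convergence and
separation are explicit errors — on a 2×2 problem the fit must reproduce
the closed-form cross-product odds ratio to $10^{-6}$, which the test
suite asserts. Confidence intervals are Wald (symmetric on the log scale);
no site-level clustering or random effects are used, matching the plain
logistic formulation this design reproduces.

## The counterfactual framework

Model 2 (same covariates, trend included, **no** era interactions) is fit
on pre-pandemic encounters only (2018-01-01 to 2020-02-29) and extrapolated
to pandemic-era encounters at their actual dates, yielding each patient's
predicted probability of sugammadex reversal under pre-pandemic practice
(contrast 2b; the active-vs-spontaneous contrast 2a is implemented and
tested but secondary). Training AUROC is reported as an accuracy gauge.

Counterfactual *labels* are then calibrated so the predicted class counts
equal the observed counts in the combined pandemic eras: encounters are
ranked by predicted probability (ties broken by encounter id) and the top
$k$ are labelled positive, $k$ being the observed positive count. Rank
top-$k$ rather than a scalar threshold guarantees exact count matching
under ties.

For each covariate level $L$ and era, a 2×2 comparison of actual vs
counterfactual labels gives

$$\text{ratio}_L = \frac{a/b}{c/d}, \qquad
\text{CI} = \exp\!\left(\ln \text{ratio}_L \pm 1.96
\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right)$$

(Woolf interval; cells with zeros get +0.5 added to all four cells and a
flag; levels with no encounters are omitted with a warning). Ratios are
normalized by a frequency-weighted scaling factor so residual
time-dependent drift of the extrapolated model cancels. Two variants are
provided because the factor admits more than one reading: the default
divides by the era's all-encounters ratio (total patient-weighted OR
exactly 1); the `"geomean"` variant divides by the encounter-weighted
geometric mean of level ratios within each covariate (weighted geometric
mean of normalized ratios exactly 1 per partition).

Calibration is performed once over the combined pandemic eras, as the
framework is described, not per era; per-era drift is absorbed by the
per-era scaling factor.

### A known artifact of count-matched hard labels

The Woolf intervals treat the actual and counterfactual label sets as
independent samples, although they label the same patients — coverage is
therefore conservative in the exchangeable case. Much more consequential
is a bias of the *hard labels themselves*: a deterministic top-$k$ rule
converts a covariate's effect on the linear predictor into a
threshold-crossing probability, whose slope ($\approx \varphi(z)/s$ for
predictor spread $s$) is roughly three times the mean-probability slope
that governs the stochastic actual outcomes at this package's default
generative conditions. Subgroups whose predicted probabilities sit above
the cutoff are over-represented among counterfactual positives, so even
with *no* generative era shock the level-wise normalized ratios deviate
systematically from 1 — by roughly $e^{-2b}$ for a level with model
coefficient $b$ — and their CIs do not attain nominal coverage. The
deviations are reproducible across seeds (correlation ≈ 0.98), i.e. a
property of the method, not noise, and their sign structure (normalized OR
above 1 for levels with negative agent-choice coefficients, below 1 for
positive ones) mirrors the subgroup deviations typically reported with
this design.

`run_counterfactual(label_method = "expected")` therefore offers an
alternative in which the counterfactual cells are model-*expected* counts
(sums of predicted probabilities) instead of hard labels. Under a
no-era-shock generative model this variant is null-faithful (≈ 99% of
level CIs contain 1 in the test suite); the hard-label default, kept for
fidelity to the count-matching formulation, is best read *relative to*
its null behaviour rather than against 1. Interpret significant
normalized ratios under the default with this artifact in mind.

## The synthetic generator

`synthetic_config()` defaults define the emulated study conditions:

* **volume and dates** — `n_encounters` uniform over 2017-03-01 to
  2021-12-31 (monthly weights configurable); the default demo size of
  100,000 keeps a full pipeline run near a minute while leaving every
  covariate level populated. Tests use 8,000–500,000 as each property
  requires.
* **covariates** — drawn independently from the baseline-period margins of
  the emulated cohort (e.g. 54.2% female, 78.3% White, 56.7% elective,
  24% obese); 13 tabulated Elixhauser comorbidity flags plus valvular
  disease (prevalence stipulated at 0.10, as it enters the models but its
  margin is not published). Sampling independence is a simplification: an
  era-specific hook (`covariate_spec` entries keyed by era) lets the
  admission-type mix shift between eras, emulating the elective-surgery
  drop of early 2020, because the counterfactual analysis is interesting
  precisely when covariate mixes shift.
* **outcomes** — the two-stage process mirrors how models 1a/1b condition:
  active-vs-spontaneous first, then agent choice among actively reversed.
  Stage coefficients default to the published model estimates (yearly
  trend ORs 1.129 and 1.388; era shocks 1.002/0.996/0.987 and
  1.008/0.992/1.001; covariate ORs per the model table). Intercepts
  (0.78, −0.75 at the anchor) were calibrated once so marginal shares
  track the observed era margins (spontaneous ≈ 27% → 22%, sugammadex ≈
  25% → 51%).
* **plumbing** — exclusion markers, dual-reversal records and 30-day
  repeat surgeries (cloned rows with 1–29-day offsets) are injected at
  small configurable rates so the filters are exercised.

What passing tests on this generator do **not** show: behaviour under
correlated covariates, site-level clustering, informative missingness, or
coding error — none of which the generator emulates.

## Numerical conventions

* Quarterly trend $R^2$ is computed on proportions (matching the visual
  linearity convention); a log-odds variant is available via
  `quarterly_trend(on = "logodds")`. A zero-variance share series has
  slope 0 and $R^2$ defined as 0.
* The washout month is removed before quarterisation, so 2020Q1 contains
  January–February only.
* Reversal classification treats `"none"` as spontaneous; dual-agent
  records are a filter responsibility and a contract violation downstream.
* Succinylcholine-free agent sets map to the long-acting-only NMB group
  regardless of how many long-acting agents appear (the three-level
  grouping has no slot for dual long-acting without succinylcholine; the
  generator gives such sets probability 0 by default).
* Era-interaction columns are requested only for eras present in the
  data; otherwise they would be identically zero and rank-deficient.
* Deterministic reproduction: one seed drives every stochastic stage, and
  `run_pipeline()` writes a config-hash-stamped manifest whose bytes are
  identical across reruns.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(
  input = synthetic_config(n_encounters = 100000),
  output_dir = "nmb-artifacts", seed = 1
)
res <- run_pipeline(cfg)
report_fit(res$fits[["1b"]])[1:4, ]
```

The first four rows of the model-1b report are the yearly trend OR and the
three era interactions; on the default generator they recover the
generative values (for instance a trend OR near 1.39) within Monte-Carlo
error, which `scripts/acceptance.R` quantifies over 50 replicates.

## Limitations

The package analyses encounter tables it is given (or generates); deriving
comorbidity flags from ICD codes, obstetric status from procedure codes,
or hospital-stay identifiers is out of scope. Inference is
complete-case and unclustered. The counterfactual framework is predictive
extrapolation, not a formal causal estimator: it quantifies deviation from
an extrapolated trend, with the label-construction caveat described above.
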