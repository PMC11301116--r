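## Defaults for the synthetic encounter generator. These are the study
## conditions the generator emulates: covariate mixes follow the published
## baseline-period margins of the cohort the pipeline targets, outcome
## coefficients follow the multivariable model estimates, and the time trend
## / era shocks are per-year log odds ratios. See the methods vignette.

default_covariate_spec <- function() {
  list(
    age_band = c(
      "18-30" = 0.068, "31-40" = 0.090, "41-50" = 0.132, "51-60" = 0.207,
      "61-70" = 0.253, "71-80" = 0.175, ">80" = 0.075
    ),
    sex = c(male = 0.458, female = 0.542),
    race = c(White = 0.783, Asian = 0.015, Black = 0.105,
             Other = 0.070, Unknown = 0.027),
    ethnicity = c(not_hispanic = 0.850, hispanic = 0.086, unknown = 0.064),
    insurance = c(commercial = 0.405, government = 0.466, low_income = 0.129),
    admission_type = c(elective = 0.567, emergency = 0.380, urgent = 0.030,
                       trauma_center = 0.023),
    surgical_type = c(
      msk_cns = 0.300, digestive = 0.250, cardiovascular = 0.120,
      urinary_male_genital = 0.050, female_genital = 0.050,
      integumentary_hemic_lymphatic = 0.040, respiratory = 0.060,
      ent = 0.030, endocrine = 0.020, eye = 0.005, other_unknown = 0.075
    ),
    bed_size = c("0-199" = 0.155, "200-399" = 0.345, "400+" = 0.500),
    teaching = c("TRUE" = 0.538, "FALSE" = 0.462),
    region = c(West = 0.146, Midwest = 0.230, Northeast = 0.142,
               South = 0.482),
    covid_history = c("TRUE" = 0.005, "FALSE" = 0.995),
    nmb_agents = c(
      "rocuronium" = 0.877,
      "vecuronium" = 0.070,
      "rocuronium+succinylcholine" = 0.045,
      "vecuronium+succinylcholine" = 0.005,
      "rocuronium+vecuronium+succinylcholine" = 0.003
    )
  )
}

default_comorbidity_prevalence <- function() {
  c(
    cardiac_arrhythmias = 0.169, chronic_pulmonary_disease = 0.185,
    congestive_heart_failure = 0.070, depression = 0.132,
    diabetes_complicated = 0.080, diabetes_uncomplicated = 0.136,
    fluid_electrolyte_disorders = 0.198, hypothyroidism = 0.122,
    obesity_overweight = 0.240, other_neurological_disorders = 0.071,
    peripheral_vascular_disorders = 0.076, sleep_apnea = 0.090,
    solid_tumor_without_metastasis = 0.118, valvular_disease = 0.100
  )
}

default_beta_covariates <- function() {
  list(
    active = list(
      nmb_group = log(c(multi_class_plus_succinylcholine = 0.469,
                        roc_or_vec_only = 1.501)),
      age_band = log(c("18-30" = 1.057, "41-50" = 0.959, "51-60" = 0.941,
                       "61-70" = 0.983, "71-80" = 1.094, ">80" = 1.349)),
      sex = log(c(female = 1.110)),
      race = log(c(Asian = 0.905, Black = 1.002, Other = 0.926,
                   Unknown = 0.938)),
      ethnicity = log(c(hispanic = 0.945, unknown = 0.910)),
      admission_type = log(c(emergency = 0.641, trauma_center = 0.612,
                             urgent = 0.668)),
      low_income = log(c("TRUE" = 0.972)),
      cm_valvular_disease = log(c("TRUE" = 0.710)),
      cm_diabetes_complicated = log(c("TRUE" = 0.870)),
      cm_cardiac_arrhythmias = log(c("TRUE" = 0.766)),
      cm_sleep_apnea = log(c("TRUE" = 1.034)),
      cm_solid_tumor_without_metastasis = log(c("TRUE" = 1.124)),
      cm_peripheral_vascular_disorders = log(c("TRUE" = 1.443)),
      cm_obesity_overweight = log(c("TRUE" = 1.013)),
      cm_congestive_heart_failure = log(c("TRUE" = 0.810)),
      cm_chronic_pulmonary_disease = log(c("TRUE" = 1.012)),
      surgical_type = log(c(female_genital = 1.877, cardiovascular = 0.372,
                            urinary_male_genital = 1.408, digestive = 2.056,
                            integumentary_hemic_lymphatic = 0.906,
                            endocrine = 0.794, eye = 1.226,
                            other_unknown = 0.981, ent = 0.702,
                            respiratory = 0.847)),
      bed_size = log(c("0-199" = 0.828, "200-399" = 0.858)),
      teaching = log(c("TRUE" = 0.971)),
      region = log(c(Midwest = 1.263, Northeast = 1.013, South = 1.203)),
      covid_history = log(c("TRUE" = 0.976))
    ),
    sug = list(
      nmb_group = log(c(multi_class_plus_succinylcholine = 0.542,
                        roc_or_vec_only = 1.421)),
      age_band = log(c("18-30" = 0.917, "41-50" = 1.042, "51-60" = 1.095,
                       "61-70" = 1.108, "71-80" = 1.137, ">80" = 1.251)),
      sex = log(c(female = 0.989)),
      race = log(c(Asian = 0.929, Black = 0.897, Other = 0.803,
                   Unknown = 0.686)),
      ethnicity = log(c(hispanic = 1.171, unknown = 1.096)),
      admission_type = log(c(emergency = 1.158, trauma_center = 1.652,
                             urgent = 1.156)),
      low_income = log(c("TRUE" = 1.069)),
      cm_valvular_disease = log(c("TRUE" = 0.940)),
      cm_diabetes_complicated = log(c("TRUE" = 1.019)),
      cm_cardiac_arrhythmias = log(c("TRUE" = 1.020)),
      cm_sleep_apnea = log(c("TRUE" = 1.034)),
      cm_solid_tumor_without_metastasis = log(c("TRUE" = 1.057)),
      cm_peripheral_vascular_disorders = log(c("TRUE" = 1.071)),
      cm_obesity_overweight = log(c("TRUE" = 1.096)),
      cm_congestive_heart_failure = log(c("TRUE" = 1.100)),
      cm_chronic_pulmonary_disease = log(c("TRUE" = 1.102)),
      surgical_type = log(c(female_genital = 0.980, cardiovascular = 1.044,
                            urinary_male_genital = 1.101, digestive = 1.115,
                            integumentary_hemic_lymphatic = 1.237,
                            endocrine = 1.326, eye = 1.531,
                            other_unknown = 1.596, ent = 1.632,
                            respiratory = 1.651)),
      bed_size = log(c("0-199" = 0.823, "200-399" = 0.864)),
      teaching = log(c("TRUE" = 1.006)),
      region = log(c(Midwest = 0.956, Northeast = 0.431, South = 0.617)),
      covid_history = log(c("TRUE" = 1.018))
    )
  )
}

#' Specify a synthetic encounter-generating process
#'
#' Builds the full generative specification for [generate_encounters()]: the
#' encounter volume and its monthly weights, the covariate mixture,
#' comorbidity prevalences, and the two-stage logistic outcome process
#' (active-vs-spontaneous reversal, then sugammadex-vs-neostigmine given
#' active reversal), each with a baseline log-odds, a linear per-year time
#' trend on the log-odds scale, per-covariate-level log odds ratios, and
#' optional era-specific trend shocks applied as era-flag-times-time
#' interactions. Rates for exclusion markers and 30-day repeat surgeries are
#' included so that the cohort filters have work to do.
#'
#' Defaults emulate the study conditions of a large US inpatient database
#' cohort, 2017-03-01 to 2021-12-31: covariate margins follow the
#' baseline-period distribution, outcome coefficients follow the fitted
#' multivariable models (for example a sugammadex-vs-neostigmine yearly
#' trend OR of 1.388), and intercepts are calibrated so marginal reversal
#' shares track the observed era margins. See the methods vignette.
#'
#' @param n_encounters Number of encounters to generate.
#' @param date_range Length-2 `Date` (or coercible) vector, start < end.
#' @param monthly_volume_weights Optional named nonnegative vector of
#'   relative volumes, names `"YYYY-MM"`; months of `date_range` not named
#'   get weight 1. `NULL` means uniform.
#' @param covariate_spec Named list: covariate -> named probability vector
#'   over its levels (must sum to 1). An entry may instead be a named list of
#'   era label -> probability vector (with a `"default"` fallback entry) to
#'   let a covariate mix shift between eras, e.g. the elective-admission drop
#'   during the early pandemic.
#' @param comorbidity_prevalence Named vector of independent Bernoulli
#'   prevalences for the flags in [comorbidity_names()].
#' @param beta0_active,beta0_sug Baseline log-odds at the 2018-01-01 time
#'   anchor for active reversal and for sugammadex given active reversal.
#' @param beta_trend_active,beta_trend_sug Per-year log odds ratios of the
#'   linear time trend for the two stages.
#' @param beta_covariates List with elements `active` and `sug`; each a named
#'   list covariate -> named vector of log odds ratios per non-reference
#'   level (levels not named contribute 0). Covariate names may be encounter
#'   columns or the derived `age_band`, `nmb_group`, `low_income`; logical
#'   covariates use level `"TRUE"`.
#' @param era_interaction List with elements `active` and `sug`; each a named
#'   vector of per-year log-OR shocks for eras `EC`, `MC`, `LC`, applied as
#'   era-flag × time interactions.
#' @param duplicate_rate Probability that a patient contributes a second
#'   surgery 1-29 days after the first (exercises deduplication).
#' @param exclusion_rates Named vector of marker probabilities over
#'   `myasthenia_gravis`, `renal_failure`, `pyridostigmine`, `obstetric`,
#'   `covid_dx`, plus `dual_reversal` (reversal recorded as both agents).
#' @param seed Integer seed; a fixed seed makes [generate_encounters()]
#'   byte-identical across runs.
#' @return An object of class `nmb_synth_config`.
#' @examples
#' cfg <- synthetic_config(n_encounters = 100, seed = 1)
#' enc <- generate_encounters(cfg)
#' @export
synthetic_config <- function(n_encounters = 100000,
                             date_range = as.Date(c("2017-03-01",
                                                    "2021-12-31")),
                             monthly_volume_weights = NULL,
                             covariate_spec = default_covariate_spec(),
                             comorbidity_prevalence =
                               default_comorbidity_prevalence(),
                             beta0_active = 0.78,
                             beta0_sug = -0.75,
                             beta_trend_active = log(1.129),
                             beta_trend_sug = log(1.388),
                             beta_covariates = default_beta_covariates(),
                             era_interaction = list(
                               active = c(EC = log(1.002), MC = log(0.996),
                                          LC = log(0.987)),
                               sug = c(EC = log(1.008), MC = log(0.992),
                                       LC = log(1.001))
                             ),
                             duplicate_rate = 0.05,
                             exclusion_rates = c(
                               myasthenia_gravis = 0.002,
                               renal_failure = 0.030,
                               pyridostigmine = 0.001,
                               obstetric = 0.020,
                               covid_dx = 0.010,
                               dual_reversal = 0.005
                             ),
                             seed = 1L) {
  cfg <- structure(
    list(
      n_encounters = as.integer(n_encounters),
      date_range = as.Date(date_range),
      monthly_volume_weights = monthly_volume_weights,
      covariate_spec = covariate_spec,
      comorbidity_prevalence = comorbidity_prevalence,
      beta0_active = beta0_active, beta0_sug = beta0_sug,
      beta_trend_active = beta_trend_active,
      beta_trend_sug = beta_trend_sug,
      beta_covariates = beta_covariates,
      era_interaction = era_interaction,
      duplicate_rate = duplicate_rate,
      exclusion_rates = exclusion_rates,
      seed = as.integer(seed)
    ),
    class = "nmb_synth_config"
  )
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (is.na(cfg$n_encounters) || cfg$n_encounters < 0) {
    stop("`n_encounters` must be a nonnegative integer", call. = FALSE)
  }
  if (length(cfg$date_range) != 2 || any(is.na(cfg$date_range)) ||
      cfg$date_range[1] >= cfg$date_range[2]) {
    stop("`date_range` must be two dates with start < end", call. = FALSE)
  }
  check_prob_vec <- function(p, covariate) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
      stop(sprintf("invalid probability for covariate '%s': out of [0,1]",
                   covariate), call. = FALSE)
    }
    if (abs(sum(p) - 1) > 1e-9) {
      stop(sprintf(
        "invalid probability mass for covariate '%s': levels sum to %.12f",
        covariate, sum(p)
      ), call. = FALSE)
    }
  }
  for (nm in names(cfg$covariate_spec)) {
    entry <- cfg$covariate_spec[[nm]]
    if (is.list(entry)) {
      lapply(entry, check_prob_vec, covariate = nm)
    } else {
      check_prob_vec(entry, nm)
    }
  }
  bad_prev <- cfg$comorbidity_prevalence < 0 | cfg$comorbidity_prevalence > 1
  if (any(bad_prev)) {
    stop(sprintf("invalid probability for covariate '%s': out of [0,1]",
                 names(cfg$comorbidity_prevalence)[bad_prev][1]),
         call. = FALSE)
  }
  rates <- c(cfg$duplicate_rate, cfg$exclusion_rates)
  if (any(rates < 0 | rates > 1)) {
    stop("duplicate_rate and exclusion_rates must lie in [0,1]",
         call. = FALSE)
  }
  if (!is.null(cfg$monthly_volume_weights) &&
      any(cfg$monthly_volume_weights < 0)) {
    stop("monthly_volume_weights must be nonnegative", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.nmb_synth_config <- function(x, ...) {
  cat("<nmb_synth_config>\n")
  cat(sprintf("  n_encounters: %d\n", x$n_encounters))
  cat(sprintf("  date_range:   %s .. %s\n", x$date_range[1], x$date_range[2]))
  cat(sprintf("  trend ORs:    active %.3f/yr, sugammadex %.3f/yr\n",
              exp(x$beta_trend_active), exp(x$beta_trend_sug)))
  cat(sprintf("  covariates:   %s\n",
              paste(names(x$covariate_spec), collapse = ", ")))
  cat(sprintf("  seed:         %d\n", x$seed))
  invisible(x)
}
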