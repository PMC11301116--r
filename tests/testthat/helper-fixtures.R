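# Fixture builders shared across the suite. Everything is constructed in
# code; no stored data.

# A single-row encounter template with sensible included-by-default values;
# make_encounters() recycles overrides across n rows.
make_encounters <- function(n = 1, ...) {
  overrides <- list(...)
  base <- list(
    encounter_id = sprintf("E%04d", seq_len(n)),
    patient_id = sprintf("P%04d", seq_len(n)),
    date = as.Date("2018-06-15"),
    age_years = 50L,
    sex = "female", race = "White", ethnicity = "not_hispanic",
    insurance = "commercial", admission_type = "elective",
    surgical_type = "digestive", bed_size = "400+", region = "South",
    teaching = TRUE, covid_history = FALSE,
    nmb_agents = "rocuronium", reversal = "sugammadex"
  )
  for (cm in nmbtrends::comorbidity_names()) {
    base[[paste0("cm_", cm)]] <- FALSE
  }
  for (mk in c("myasthenia_gravis", "renal_failure", "pyridostigmine",
               "obstetric", "covid_dx")) {
    base[[paste0("excl_", mk)]] <- FALSE
  }
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  tibble::as_tibble(lapply(base, function(v) rep(v, length.out = n)))
}

# Analysis-ready cohort rows without running the full selection sequence;
# used by model and counterfactual unit tests.
make_cohort <- function(n, date, reversal_class, ...) {
  out <- tibble::tibble(
    encounter_id = sprintf("E%05d", seq_len(n)),
    date = rep(as.Date(date), length.out = n),
    reversal_class = factor(rep(reversal_class, length.out = n),
                            levels = c("sugammadex", "neostigmine",
                                       "spontaneous"))
  )
  out$era <- factor(as.character(assign_era(out$date)),
                    levels = c("BP", "BC", "EC", "MC", "LC"))
  out$t <- time_covariate(out$date)
  out$active <- out$reversal_class != "spontaneous"
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- rep(extra[[nm]], length.out = n)
  out
}

# Generator configuration used for parameter recovery and null-scenario
# checks: 2018-2021 window, the published sugammadex-vs-neostigmine trend
# and era-shock coefficients, and a reduced covariate set (age band, sex,
# admission type) so the fitted model is exactly the generative one.
recovery_config <- function(n, seed,
                            era_sug = c(EC = log(1.008), MC = log(0.992),
                                        LC = log(1.001)),
                            era_active = c(EC = log(1.002),
                                           MC = log(0.996),
                                           LC = log(0.987))) {
  synthetic_config(
    n_encounters = n, seed = seed,
    date_range = as.Date(c("2018-01-01", "2021-12-31")),
    beta_covariates = recovery_betas(),
    era_interaction = list(active = era_active, sug = era_sug),
    duplicate_rate = 0,
    exclusion_rates = c(
      myasthenia_gravis = 0, renal_failure = 0, pyridostigmine = 0,
      obstetric = 0, covid_dx = 0, dual_reversal = 0
    )
  )
}

recovery_betas <- function() {
  list(
    active = list(
      age_band = log(c("18-30" = 1.057, "41-50" = 0.959, "51-60" = 0.941,
                       "61-70" = 0.983, "71-80" = 1.094, ">80" = 1.349)),
      sex = log(c(female = 1.110)),
      admission_type = log(c(emergency = 0.641, trauma_center = 0.612,
                             urgent = 0.668))
    ),
    sug = list(
      age_band = log(c("18-30" = 0.917, "41-50" = 1.042, "51-60" = 1.095,
                       "61-70" = 1.108, "71-80" = 1.137, ">80" = 1.251)),
      sex = log(c(female = 0.989)),
      admission_type = log(c(emergency = 1.158, trauma_center = 1.652,
                             urgent = 1.156))
    )
  )
}

recovery_spec <- function(outcome = "sugammadex_vs_neostigmine") {
  model_spec(
    outcome,
    covariates = list(age_band = "31-40", sex = "male",
                      admission_type = "elective")
  )
}

# True log odds ratios of the model-1b terms under recovery_config().
recovery_truth_1b <- function(cfg) {
  b <- cfg$beta_covariates$sug
  c(
    t = cfg$beta_trend_sug,
    `t:era_EC` = unname(cfg$era_interaction$sug["EC"]),
    `t:era_MC` = unname(cfg$era_interaction$sug["MC"]),
    `t:era_LC` = unname(cfg$era_interaction$sug["LC"]),
    stats::setNames(unname(b$age_band),
                    paste0("age_band=", names(b$age_band))),
    stats::setNames(unname(b$sex), paste0("sex=", names(b$sex))),
    stats::setNames(unname(b$admission_type),
                    paste0("admission_type=", names(b$admission_type)))
  )
}
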