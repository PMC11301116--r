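#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Canonical level sets for every categorical field of an encounter record.
## These mirror the covariate levels used throughout the stratified tables and
## the multivariable models; reference levels for modelling live in
## `default_covariate_terms()` (trend-models.R).

nmb_levels <- function() {
  list(
    age_band = c("18-30", "31-40", "41-50", "51-60", "61-70", "71-80", ">80"),
    sex = c("male", "female"),
    race = c("White", "Asian", "Black", "Other", "Unknown"),
    ethnicity = c("not_hispanic", "hispanic", "unknown"),
    insurance = c("commercial", "government", "low_income"),
    admission_type = c("elective", "emergency", "urgent", "trauma_center"),
    surgical_type = c(
      "msk_cns", "female_genital", "cardiovascular", "urinary_male_genital",
      "digestive", "integumentary_hemic_lymphatic", "endocrine", "eye",
      "other_unknown", "ent", "respiratory"
    ),
    bed_size = c("0-199", "200-399", "400+"),
    region = c("West", "Midwest", "Northeast", "South"),
    reversal = c("sugammadex", "neostigmine", "none", "both"),
    reversal_class = c("sugammadex", "neostigmine", "spontaneous"),
    nmb_group = c(
      "roc_or_vec_plus_succinylcholine",
      "roc_or_vec_only",
      "multi_class_plus_succinylcholine"
    ),
    era = c("BP", "BC", "EC", "MC", "LC", "washout", "out_of_study")
  )
}

#' Comorbidity flag names carried by encounter records
#'
#' The thirteen most frequent Elixhauser comorbidity categories tabulated for
#' this cohort, plus valvular disease, which enters the multivariable models.
#' Flags are boolean columns named `cm_<name>`.
#'
#' @return Character vector of bare comorbidity names (without the `cm_`
#'   prefix).
#' @export
comorbidity_names <- function() {
  c(
    "cardiac_arrhythmias", "chronic_pulmonary_disease",
    "congestive_heart_failure", "depression", "diabetes_complicated",
    "diabetes_uncomplicated", "fluid_electrolyte_disorders", "hypothyroidism",
    "obesity_overweight", "other_neurological_disorders",
    "peripheral_vascular_disorders", "sleep_apnea",
    "solid_tumor_without_metastasis", "valvular_disease"
  )
}

exclusion_marker_names <- function() {
  c("myasthenia_gravis", "renal_failure", "pyridostigmine", "obstetric",
    "covid_dx")
}

## Full column contract for the encounter CSV, in write order.
encounter_schema <- function() {
  lv <- nmb_levels()
  cats <- list(
    sex = lv$sex, race = lv$race, ethnicity = lv$ethnicity,
    insurance = lv$insurance, admission_type = lv$admission_type,
    surgical_type = lv$surgical_type, bed_size = lv$bed_size,
    region = lv$region, reversal = lv$reversal
  )
  list(
    character = c("encounter_id", "patient_id", "nmb_agents"),
    date = "date",
    integer = "age_years",
    categorical = cats,
    logical = c(
      "teaching", "covid_history",
      paste0("cm_", comorbidity_names()),
      paste0("excl_", exclusion_marker_names())
    )
  )
}

encounter_columns <- function() {
  sc <- encounter_schema()
  c("encounter_id", "patient_id", "date", "age_years",
    names(sc$categorical)[names(sc$categorical) != "reversal"],
    "teaching", "covid_history",
    paste0("cm_", comorbidity_names()),
    "nmb_agents", "reversal",
    paste0("excl_", exclusion_marker_names()))
}

## Case-insensitive canonicalization of a character vector against a level
## set; unmatched values come back as NA so the caller can report rows.
canonicalize_levels <- function(x, levels) {
  idx <- match(tolower(trimws(x)), tolower(levels))
  levels[idx]
}

## Age bands used for both generation and modelling.
age_to_band <- function(age_years) {
  lv <- nmb_levels()$age_band
  cut(age_years,
    breaks = c(17, 30, 40, 50, 60, 70, 80, Inf),
    labels = lv
  )
}

## nmb_agents is stored as agents joined by "+" in fixed order.
nmb_agent_set <- function() c("rocuronium", "vecuronium", "succinylcholine")

encode_agents <- function(agent_list) {
  vapply(agent_list, function(a) {
    paste(intersect(nmb_agent_set(), a), collapse = "+")
  }, character(1))
}

decode_agents <- function(x) strsplit(x, "+", fixed = TRUE)
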