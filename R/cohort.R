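exclusion_reason_order <- function() {
  c("age", "agents", "myasthenia_gravis", "renal_failure", "pyridostigmine",
    "dual_reversal", "obstetric", "covid_dx", "washout", "out_of_study")
}

#' Apply cohort inclusion and exclusion rules
#'
#' Retains adult encounters (age >= 18) that received rocuronium or
#' vecuronium, and removes encounters with a myasthenia gravis or renal
#' failure diagnosis, pyridostigmine therapy, reversal recorded with both
#' sugammadex and neostigmine, obstetric procedures, a COVID-19 diagnosis
#' (applied to encounters dated 2020-2021 only), and encounters falling in
#' the March-2020 washout month or outside the study window. Reasons are
#' checked in that fixed order and each removed row counts under its first
#' matching reason, so the attrition report reconciles exactly:
#' input = retained + sum of per-reason removals.
#'
#' @param encounters Encounter tibble (see [read_encounters()]).
#' @param windows Era window table, default [era_windows()].
#' @return A list with `cohort` (the retained rows) and `report`, an
#'   `nmb_filter_report` with `n_input`, `n_retained`, `counts_removed`
#'   (named by reason) and `counts_retained_per_era`.
#' @export
apply_filters <- function(encounters, windows = era_windows()) {
  n <- nrow(encounters)
  era <- assign_era(encounters$date, windows)
  yr <- as.integer(format(encounters$date, "%Y"))
  has_long_acting <- grepl("rocuronium", encounters$nmb_agents,
                           fixed = TRUE) |
    grepl("vecuronium", encounters$nmb_agents, fixed = TRUE)

  checks <- list(
    age = encounters$age_years < 18,
    agents = !has_long_acting,
    myasthenia_gravis = encounters$excl_myasthenia_gravis,
    renal_failure = encounters$excl_renal_failure,
    pyridostigmine = encounters$excl_pyridostigmine,
    dual_reversal = encounters$reversal == "both",
    obstetric = encounters$excl_obstetric,
    covid_dx = encounters$excl_covid_dx & yr %in% c(2020L, 2021L),
    washout = era == "washout",
    out_of_study = era == "out_of_study"
  )
  reason <- rep(NA_character_, n)
  for (r in exclusion_reason_order()) {
    hit <- checks[[r]] & is.na(reason)
    reason[hit] <- r
  }

  retained <- is.na(reason)
  counts_removed <- vapply(
    exclusion_reason_order(),
    function(r) sum(reason == r, na.rm = TRUE), integer(1)
  )
  per_era <- table(factor(as.character(era[retained]),
                          levels = c("BP", "BC", "EC", "MC", "LC")))
  report <- structure(
    list(
      n_input = n,
      n_retained = sum(retained),
      counts_removed = counts_removed,
      counts_retained_per_era = as.integer(per_era) |>
        stats::setNames(names(per_era))
    ),
    class = "nmb_filter_report"
  )
  list(cohort = encounters[retained, , drop = FALSE], report = report)
}

#' @export
print.nmb_filter_report <- function(x, ...) {
  cat("<nmb_filter_report>\n")
  cat(sprintf("  input: %d   retained: %d\n", x$n_input, x$n_retained))
  rem <- x$counts_removed[x$counts_removed > 0]
  if (length(rem) > 0) {
    cat("  removed:\n")
    for (r in names(rem)) cat(sprintf("    %-18s %d\n", r, rem[[r]]))
  }
  cat("  retained per era:",
      paste(sprintf("%s=%d", names(x$counts_retained_per_era),
                    x$counts_retained_per_era), collapse = " "), "\n")
  invisible(x)
}

#' Keep only each patient's first surgery in any rolling 30-day window
#'
#' Scanning each patient's encounters in date order, a row is kept iff no
#' already-kept row for that patient lies within the preceding 29 days;
#' equivalently, a gap of at least 30 days from the last kept surgery admits
#' the next one. The kept set is deterministic and invariant to input row
#' order (ties broken by `encounter_id`); the operation is idempotent.
#'
#' @param encounters Encounter tibble with `patient_id`, `date`,
#'   `encounter_id`.
#' @return The retained rows, in (patient, date, encounter_id) order.
#' @export
deduplicate_first_surgery <- function(encounters) {
  if (nrow(encounters) == 0) return(encounters)
  ord <- order(encounters$patient_id, encounters$date,
               encounters$encounter_id)
  x <- encounters[ord, , drop = FALSE]
  pid <- x$patient_id
  day <- as.numeric(x$date)
  keep <- rep(TRUE, nrow(x))
  runs <- rle(pid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (g in which(runs$lengths > 1L)) {
    idx <- starts[g]:ends[g]
    anchor <- day[idx[1]]
    for (i in idx[-1]) {
      if (day[i] - anchor >= 30) {
        anchor <- day[i]
      } else {
        keep[i] <- FALSE
      }
    }
  }
  x[keep, , drop = FALSE]
}

#' Classify the reversal strategy of filtered encounters
#'
#' Maps the recorded reversal field to the three-level analysis outcome:
#' `sugammadex`, `neostigmine`, or `spontaneous` (no active pharmacologic
#' reversal). Dual-agent records are an exclusion criterion and must have
#' been removed by [apply_filters()] first; encountering one here is an
#' error.
#'
#' @param encounters Post-filter encounter tibble.
#' @return Factor with levels `sugammadex`, `neostigmine`, `spontaneous`.
#' @export
classify_reversal <- function(encounters) {
  rev <- encounters$reversal
  if (any(rev == "both")) {
    stop("encounters with dual (sugammadex + neostigmine) reversal present; ",
         "run apply_filters() first", call. = FALSE)
  }
  out <- ifelse(rev == "none", "spontaneous", rev)
  factor(out, levels = nmb_levels()$reversal_class)
}

nmb_group_from_agents <- function(nmb_agents) {
  n_long <- grepl("rocuronium", nmb_agents, fixed = TRUE) +
    grepl("vecuronium", nmb_agents, fixed = TRUE)
  has_succ <- grepl("succinylcholine", nmb_agents, fixed = TRUE)
  out <- ifelse(
    !has_succ, "roc_or_vec_only",
    ifelse(n_long >= 2, "multi_class_plus_succinylcholine",
           "roc_or_vec_plus_succinylcholine")
  )
  out[n_long == 0] <- NA_character_
  factor(out, levels = nmb_levels()$nmb_group)
}

#' Classify the NMB agent combination
#'
#' Groups each encounter's agent set into the three modelling levels:
#' `roc_or_vec_only` (a long-acting agent without succinylcholine),
#' `roc_or_vec_plus_succinylcholine` (exactly one long-acting agent with
#' succinylcholine; the model reference level), and
#' `multi_class_plus_succinylcholine` (both long-acting agents plus
#' succinylcholine). Encounters without rocuronium or vecuronium violate the
#' inclusion contract and raise an error.
#'
#' @param encounters Encounter tibble (post-filter).
#' @return Factor with the three group levels.
#' @export
classify_nmb_group <- function(encounters) {
  out <- nmb_group_from_agents(encounters$nmb_agents)
  if (anyNA(out)) {
    stop("encounter without rocuronium or vecuronium; run apply_filters() ",
         "first", call. = FALSE)
  }
  out
}

#' Build the analysis cohort from raw encounters
#'
#' Runs the full selection sequence — [apply_filters()], then
#' [deduplicate_first_surgery()] — and attaches the derived analysis
#' columns: `era`, the continuous time covariate `t` (fractional years since
#' 2018-01-01), `reversal_class`, `active`, `nmb_group`, `age_band`, and
#' `low_income`.
#'
#' @param encounters Raw encounter tibble.
#' @param windows Era window table, default [era_windows()].
#' @return A list with `cohort` (analysis-ready tibble) and `report` (the
#'   [apply_filters()] attrition report).
#' @examples
#' enc <- generate_encounters(synthetic_config(n_encounters = 500, seed = 2))
#' ch <- build_cohort(enc)
#' ch$report
#' @export
build_cohort <- function(encounters, windows = era_windows()) {
  filtered <- apply_filters(encounters, windows)
  cohort <- deduplicate_first_surgery(filtered$cohort)
  cohort$era <- factor(as.character(assign_era(cohort$date, windows)),
                       levels = c("BP", "BC", "EC", "MC", "LC"))
  cohort$t <- time_covariate(cohort$date)
  cohort$reversal_class <- classify_reversal(cohort)
  cohort$active <- cohort$reversal_class != "spontaneous"
  cohort$nmb_group <- classify_nmb_group(cohort)
  cohort$age_band <- age_to_band(cohort$age_years)
  cohort$low_income <- cohort$insurance == "low_income"
  list(cohort = cohort, report = filtered$report)
}
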