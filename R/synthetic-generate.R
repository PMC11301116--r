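## Run `expr` under the config seed without disturbing the caller's RNG
## stream.
with_config_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

empty_encounters <- function() {
  sc <- encounter_schema()
  cols <- encounter_columns()
  out <- lapply(cols, function(cl) {
    if (cl %in% sc$character) character(0)
    else if (cl == "date") as.Date(character(0))
    else if (cl == "age_years") integer(0)
    else if (cl %in% names(sc$categorical)) character(0)
    else logical(0)
  })
  names(out) <- cols
  tibble::as_tibble(out)
}

## Month table covering the date range, with per-month sampling weight and
## the in-range day span.
month_table <- function(date_range, weights) {
  first <- as.Date(format(date_range[1], "%Y-%m-01"))
  months <- seq(first, date_range[2], by = "month")
  key <- format(months, "%Y-%m")
  w <- rep(1, length(months))
  if (!is.null(weights)) {
    hit <- match(names(weights), key)
    if (anyNA(hit)) {
      stop("monthly_volume_weights names must be 'YYYY-MM' within date_range",
           call. = FALSE)
    }
    w[hit] <- unname(weights)
  }
  month_end <- seq(first, by = "month", length.out = length(months) + 1)[-1] - 1
  tibble::tibble(
    month = key,
    start = pmax(months, date_range[1]),
    end = pmin(month_end, date_range[2]),
    weight = w
  )
}

sample_dates <- function(n, date_range, weights) {
  mt <- month_table(date_range, weights)
  if (all(mt$weight == 0)) stop("all monthly volume weights are zero",
                                call. = FALSE)
  idx <- sample.int(nrow(mt), n, replace = TRUE, prob = mt$weight)
  span <- as.integer(mt$end - mt$start) + 1L
  offset <- floor(stats::runif(n) * span[idx])
  mt$start[idx] + offset
}

sample_levels <- function(entry, n, era, covariate) {
  draw <- function(p, m) {
    sample(names(p), m, replace = TRUE, prob = unname(p))
  }
  if (!is.list(entry)) return(draw(entry, n))
  out <- character(n)
  for (lab in unique(as.character(era))) {
    rows <- which(as.character(era) == lab)
    p <- entry[[lab]]
    if (is.null(p)) p <- entry[["default"]]
    if (is.null(p)) {
      stop(sprintf(
        "era-specific spec for covariate '%s' lacks era '%s' and no 'default'",
        covariate, lab
      ), call. = FALSE)
    }
    out[rows] <- draw(p, length(rows))
  }
  out
}

band_to_age <- function(band) {
  lo <- c("18-30" = 18, "31-40" = 31, "41-50" = 41, "51-60" = 51,
          "61-70" = 61, "71-80" = 71, ">80" = 81)
  hi <- c("18-30" = 30, "31-40" = 40, "41-50" = 50, "51-60" = 60,
          "61-70" = 70, "71-80" = 80, ">80" = 89)
  lo[band] + floor(stats::runif(length(band)) * (hi[band] - lo[band] + 1L))
}

## Sum the per-level log-OR contributions of `betas` (a named list
## covariate -> named vector) over the rows of `frame`.
linear_predictor_covariates <- function(frame, betas) {
  lp <- numeric(nrow(frame))
  for (cov in names(betas)) {
    if (!cov %in% names(frame)) {
      stop(sprintf("beta_covariates names unknown covariate '%s'", cov),
           call. = FALSE)
    }
    b <- betas[[cov]]
    values <- frame[[cov]]
    if (!is.character(values)) values <- as.character(values)
    contrib <- b[match(values, names(b))]
    contrib[is.na(contrib)] <- 0
    lp <- lp + unname(contrib)
  }
  lp
}

## Full generative linear predictor for one outcome stage.
generative_linear_predictor <- function(frame, beta0, beta_trend, betas,
                                        era_shock) {
  t <- time_covariate(frame$date)
  lp <- beta0 + beta_trend * t + linear_predictor_covariates(frame, betas)
  if (length(era_shock) == 0) return(lp)
  era <- as.character(assign_era(frame$date))
  shock <- era_shock[match(era, names(era_shock))]
  shock[is.na(shock)] <- 0
  lp + unname(shock) * t
}

#' Generate synthetic surgical encounters
#'
#' Draws `n_encounters` encounter records from the generative process in a
#' [synthetic_config()]: encounter dates proportional to monthly volume
#' weights (uniform within month), covariates drawn independently from the
#' configured mixtures (optionally era-specific), and the reversal outcome
#' from the two-stage logistic process — active-vs-spontaneous first, then
#' sugammadex-vs-neostigmine among actively reversed encounters — whose
#' linear predictors combine baseline log-odds, the per-year time trend
#' (anchored at 2018-01-01), covariate log odds ratios, and era-by-time
#' shocks. Exclusion markers, dual-reversal records, and 30-day repeat
#' surgeries (cloned rows with a 1-29 day offset and a shared patient id)
#' are injected at the configured rates so the cohort filters are
#' exercised.
#'
#' @param config An `nmb_synth_config` object.
#' @return A tibble of encounters, one row per surgical procedure, with the
#'   columns of [read_encounters()]'s contract. Deterministic given
#'   `config$seed`.
#' @examples
#' enc <- generate_encounters(synthetic_config(n_encounters = 50, seed = 7))
#' dplyr::count(enc, reversal)
#' @export
generate_encounters <- function(config) {
  stopifnot(inherits(config, "nmb_synth_config"))
  validate_synth_config(config)
  n <- config$n_encounters
  if (n == 0) return(empty_encounters())

  with_config_seed(config$seed, {
    n_dup <- stats::rbinom(1, n, config$duplicate_rate)
    n_base <- n - n_dup

    date <- sample_dates(n_base, config$date_range,
                         config$monthly_volume_weights)
    era <- assign_era(date)

    frame <- tibble::tibble(date = date)
    for (cov in names(config$covariate_spec)) {
      frame[[cov]] <- sample_levels(config$covariate_spec[[cov]], n_base,
                                    era, cov)
    }
    frame$age_years <- as.integer(band_to_age(frame$age_band))
    frame$teaching <- frame$teaching == "TRUE"
    frame$covid_history <- frame$covid_history == "TRUE"

    prev <- config$comorbidity_prevalence
    for (cm in names(prev)) {
      frame[[paste0("cm_", cm)]] <- stats::runif(n_base) < prev[[cm]]
    }

    # derived covariates available to the outcome linear predictors
    frame$nmb_group <- as.character(nmb_group_from_agents(frame$nmb_agents))
    frame$low_income <- frame$insurance == "low_income"

    lp_active <- generative_linear_predictor(
      frame, config$beta0_active, config$beta_trend_active,
      config$beta_covariates$active, config$era_interaction$active
    )
    active <- stats::runif(n_base) < stats::plogis(lp_active)
    lp_sug <- generative_linear_predictor(
      frame, config$beta0_sug, config$beta_trend_sug,
      config$beta_covariates$sug, config$era_interaction$sug
    )
    sug <- stats::runif(n_base) < stats::plogis(lp_sug)
    frame$reversal <- ifelse(active, ifelse(sug, "sugammadex", "neostigmine"),
                             "none")

    rates <- config$exclusion_rates
    dual <- stats::runif(n_base) < rates[["dual_reversal"]]
    frame$reversal[dual & active] <- "both"
    for (mk in exclusion_marker_names()) {
      frame[[paste0("excl_", mk)]] <- stats::runif(n_base) < rates[[mk]]
    }

    frame$patient_id <- sprintf("P%08d", seq_len(n_base))

    if (n_dup > 0) {
      src <- sample.int(n_base, n_dup, replace = TRUE)
      clones <- frame[src, ]
      offset <- 1L + floor(stats::runif(n_dup) * 29)
      clones$date <- pmin(clones$date + offset, config$date_range[2])
      frame <- dplyr::bind_rows(frame, clones)
    }
    frame$encounter_id <- sprintf("E%08d", seq_len(n))

    dplyr::select(frame, dplyr::all_of(encounter_columns()))
  })
}
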