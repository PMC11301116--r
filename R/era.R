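#' Study era windows
#'
#' Calendar windows defining the five study eras and the transition washout
#' month. The study spans 2017-03-01 to 2021-12-31: a two-year baseline
#' period (BP), a pre-pandemic year (BC), and three pandemic eras — early
#' (EC), middle (MC) and late (LC) COVID-19. March 2020 is omitted as a
#' transition washout. All bounds are inclusive.
#'
#' @return A tibble with columns `era`, `start`, `end` (class `Date`), one
#'   row per window including `washout`.
#' @examples
#' era_windows()
#' @export
era_windows <- function() {
  tibble::tibble(
    era = c("BP", "BC", "washout", "EC", "MC", "LC"),
    start = as.Date(c(
      "2017-03-01", "2019-03-01", "2020-03-01",
      "2020-04-01", "2020-08-01", "2021-01-01"
    )),
    end = as.Date(c(
      "2019-02-28", "2020-02-29", "2020-03-31",
      "2020-07-31", "2020-12-31", "2021-12-31"
    ))
  )
}

#' Assign study eras to calendar dates
#'
#' Total function on dates: every date maps to exactly one of the five era
#' labels, `"washout"` (March 2020) or `"out_of_study"` (outside
#' 2017-03-01..2021-12-31).
#'
#' @param date A `Date` vector.
#' @param windows Era window table, default [era_windows()].
#' @return A factor with levels `BP, BC, EC, MC, LC, washout, out_of_study`.
#' @examples
#' assign_era(as.Date(c("2017-03-01", "2020-03-15", "2016-12-31")))
#' @export
assign_era <- function(date, windows = era_windows()) {
  stopifnot(inherits(date, "Date"))
  win <- windows
  out <- rep("out_of_study", length(date))
  for (i in seq_len(nrow(win))) {
    hit <- !is.na(date) & date >= win$start[i] & date <= win$end[i]
    out[hit] <- win$era[i]
  }
  out[is.na(date)] <- NA_character_
  factor(out, levels = nmb_levels()$era)
}

#' Continuous time covariate in fractional years
#'
#' The model time axis: days since the 2018-01-01 anchor divided by 365.25,
#' so that the exponentiated trend coefficient is a per-year odds ratio.
#' Dates before the anchor give negative values.
#'
#' @param date A `Date` vector.
#' @param anchor Anchor date (default `"2018-01-01"`). Shifting the anchor
#'   changes only a fitted model's intercept, never trend or interaction
#'   odds ratios.
#' @return Numeric vector of fractional years.
#' @examples
#' time_covariate(as.Date("2020-06-01"))
#' @export
time_covariate <- function(date, anchor = as.Date("2018-01-01")) {
  as.numeric(date - as.Date(anchor)) / 365.25
}

covid_eras <- function() c("EC", "MC", "LC")
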