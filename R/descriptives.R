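#' Stratified count/percentage table by era
#'
#' Cross-tabulates a cohort column against study era, reporting the exact
#' cell count and the percent of the era's column total (plus a pooled
#' `Total` column). Percentages are returned unrounded; round to one decimal
#' for display. An era with no encounters yields missing percentages with a
#' warning.
#'
#' @param cohort Analysis cohort (see [build_cohort()]), classified by era.
#' @param row_var Name of the column to stratify (e.g. `"reversal_class"`,
#'   `"age_band"`, `"admission_type"`).
#' @return A tibble with columns `level`, `era`, `n`, `pct`.
#' @examples
#' ch <- build_cohort(generate_encounters(
#'   synthetic_config(n_encounters = 2000, seed = 3)))$cohort
#' strat_table(ch, "reversal_class")
#' @export
strat_table <- function(cohort, row_var) {
  if (!row_var %in% names(cohort)) {
    stop(sprintf("column '%s' not present in cohort", row_var), call. = FALSE)
  }
  eras <- c("BP", "BC", "EC", "MC", "LC")
  lev <- cohort[[row_var]]
  if (!is.factor(lev)) lev <- factor(lev)
  era <- factor(as.character(cohort$era), levels = eras)
  counts <- unclass(table(lev, era))
  mat <- cbind(counts, Total = rowSums(counts))
  totals <- colSums(mat)
  if (any(totals == 0)) {
    warning(sprintf("era column(s) with no encounters: %s",
                    paste(colnames(mat)[totals == 0], collapse = ", ")),
            call. = FALSE)
  }
  out <- tibble::tibble(
    level = rep(rownames(mat), times = ncol(mat)),
    era = factor(rep(colnames(mat), each = nrow(mat)),
                 levels = c(eras, "Total")),
    n = as.integer(mat),
    pct = 100 * as.vector(mat) / rep(unname(totals), each = nrow(mat))
  )
  out$pct[rep(unname(totals), each = nrow(mat)) == 0] <- NA_real_
  out
}

quarter_label <- function(date) {
  q <- (as.integer(format(date, "%m")) - 1L) %/% 3L + 1L
  sprintf("%sQ%d", format(date, "%Y"), q)
}

quarter_index <- function(label, origin = "2018Q1") {
  yr <- as.integer(substr(label, 1, 4))
  q <- as.integer(substr(label, 6, 6))
  oy <- as.integer(substr(origin, 1, 4))
  oq <- as.integer(substr(origin, 6, 6))
  (yr - oy) * 4L + (q - oq)
}

#' Quarterly reversal-share series with linear trend fit
#'
#' Computes the per-calendar-quarter share of encounters using a given
#' reversal strategy and fits an ordinary least-squares line to the shares
#' from 2018Q1 onward, the window over which the reversal trends are
#' approximately linear. March-2020 encounters are removed upstream by the
#' cohort filters, so 2020Q1 contains January-February only.
#'
#' @param cohort Analysis cohort with `date` and `reversal_class`.
#' @param strategy One of `"sugammadex"`, `"neostigmine"`, `"spontaneous"`,
#'   or `"active"` (sugammadex or neostigmine).
#' @param on Scale for the fit: `"proportion"` (default, matching the
#'   visual-linearity convention) or `"logodds"`.
#' @return An `nmb_quarterly_trend` list: `series` (tibble with `quarter`,
#'   `quarter_index`, `n`, `share`, `in_fit`), `slope`, `intercept`,
#'   `r_squared`, `strategy`, `on`. A zero-variance share series has slope 0
#'   and, by convention, `r_squared = 0`. Fewer than two fit quarters is an
#'   error.
#' @examples
#' ch <- build_cohort(generate_encounters(
#'   synthetic_config(n_encounters = 5000, seed = 4)))$cohort
#' quarterly_trend(ch, "sugammadex")$r_squared
#' @export
quarterly_trend <- function(cohort, strategy = "sugammadex",
                            on = c("proportion", "logodds")) {
  on <- match.arg(on)
  strategy <- match.arg(strategy, c("sugammadex", "neostigmine",
                                    "spontaneous", "active"))
  hit <- if (strategy == "active") {
    cohort$reversal_class != "spontaneous"
  } else {
    cohort$reversal_class == strategy
  }
  qt <- quarter_label(cohort$date)
  agg <- stats::aggregate(hit, by = list(quarter = qt),
                          FUN = function(z) c(n = length(z), k = sum(z)))
  series <- tibble::tibble(
    quarter = agg$quarter,
    quarter_index = quarter_index(agg$quarter),
    n = as.integer(agg$x[, "n"]),
    share = agg$x[, "k"] / agg$x[, "n"]
  )
  series <- series[order(series$quarter_index), ]
  series$in_fit <- series$quarter_index >= 0 & series$n > 0
  fit_rows <- series[series$in_fit, ]
  if (nrow(fit_rows) < 2) {
    stop("insufficient series: need at least two quarters with encounters ",
         "from 2018Q1 onward", call. = FALSE)
  }
  y <- if (on == "logodds") {
    stats::qlogis(pmin(pmax(fit_rows$share, 1e-12), 1 - 1e-12))
  } else {
    fit_rows$share
  }
  x <- fit_rows$quarter_index
  if (stats::var(y) == 0) {
    slope <- 0; intercept <- mean(y); r2 <- 0
  } else {
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  }
  structure(
    list(series = series, slope = slope, intercept = intercept,
         r_squared = r2, strategy = strategy, on = on),
    class = "nmb_quarterly_trend"
  )
}

#' @export
print.nmb_quarterly_trend <- function(x, ...) {
  cat(sprintf(
    "<nmb_quarterly_trend> strategy=%s scale=%s\n  %d quarters (%d in fit); slope %.5f per quarter; R^2 = %.4f\n",
    x$strategy, x$on, nrow(x$series), sum(x$series$in_fit), x$slope,
    x$r_squared
  ))
  invisible(x)
}
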