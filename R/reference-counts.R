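#' Study-scale reversal margins by era
#'
#' Aggregate encounter counts by era and reversal strategy for the US
#' inpatient study population this pipeline is designed around
#' (2017-03-01 to 2021-12-31, roughly 3.6 million encounters). Shipped as a
#' small plain-text fixture; the descriptive module reconstructs every
#' published era percentage from these cells.
#'
#' @return A tibble with columns `era`, `reversal_class`, `n`.
#' @examples
#' reference_reversal_counts()
#' @export
reference_reversal_counts <- function() {
  path <- system.file("extdata", "reversal_counts_by_era.csv",
                      package = "nmbtrends", mustWork = TRUE)
  readr::read_csv(path, col_types = "cci", progress = FALSE)
}

#' Expand era-level margins into a minimal encounter-level cohort
#'
#' Builds the smallest cohort consistent with a table of (era,
#' reversal_class, n) margins: one row per encounter carrying only the two
#' classification columns. Useful for exercising [strat_table()] against
#' known aggregate counts.
#'
#' @param counts Tibble with columns `era`, `reversal_class`, `n`.
#' @return A tibble with factor columns `era` and `reversal_class`,
#'   `sum(counts$n)` rows.
#' @export
cohort_from_margins <- function(counts) {
  idx <- rep(seq_len(nrow(counts)), counts$n)
  tibble::tibble(
    era = factor(counts$era[idx], levels = c("BP", "BC", "EC", "MC", "LC")),
    reversal_class = factor(counts$reversal_class[idx],
                            levels = nmb_levels()$reversal_class)
  )
}
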