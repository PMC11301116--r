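#' Write and read encounter tables
#'
#' Encounters travel as plain delimited text (CSV) with a fixed, documented
#' header (see [read_encounters()] for the column contract). The round trip
#' `read_encounters(write_encounters(x, path))` is lossless, including
#' categorical levels, logical flags and dates.
#'
#' @param encounters An encounter tibble as produced by
#'   [generate_encounters()] or [read_encounters()].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_encounters <- function(encounters, path) {
  missing <- setdiff(encounter_columns(), names(encounters))
  if (length(missing) > 0) {
    stop(sprintf("encounters table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- encounters[, encounter_columns()]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_encounters
#'
#' @details
#' `read_encounters()` validates the file against the encounter contract:
#' columns `encounter_id`, `patient_id`, `date` (ISO-8601), `age_years`,
#' the categorical fields (`sex`, `race`, `ethnicity`, `insurance`,
#' `admission_type`, `surgical_type`, `bed_size`, `region`, `reversal`),
#' logical flags (`teaching`, `covid_history`, the `cm_*` comorbidity flags
#' and `excl_*` exclusion markers), and `nmb_agents` (agents joined by
#' `"+"`). Categorical values and agent names are matched
#' case-insensitively and canonicalized; an unknown column, an unparseable
#' date, or a value outside a field's level set raises an error naming the
#' offending column and data row.
#'
#' @return For `read_encounters()`, a validated encounter tibble.
#' @export
read_encounters <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  cols <- encounter_columns()
  missing <- setdiff(cols, names(raw))
  if (length(missing) > 0) {
    stop(sprintf("encounter file is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  unknown <- setdiff(names(raw), cols)
  if (length(unknown) > 0) {
    stop(sprintf("encounter file has unknown column(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  sc <- encounter_schema()

  fail_rows <- function(bad, column, what) {
    if (any(bad)) {
      rows <- which(bad)
      stop(sprintf(
        "%s in column '%s' at data row(s) %s", what, column,
        paste(utils::head(rows, 5), collapse = ", ")
      ), call. = FALSE)
    }
  }

  out <- tibble::tibble(.rows = nrow(raw))
  for (cl in cols) {
    x <- raw[[cl]]
    if (cl %in% sc$character && cl != "nmb_agents") {
      out[[cl]] <- x
    } else if (cl == "date") {
      d <- as.Date(x, format = "%Y-%m-%d")
      fail_rows(is.na(d) & !is.na(x), cl, "unparseable date")
      fail_rows(is.na(x), cl, "missing value")
      out[[cl]] <- d
    } else if (cl == "age_years") {
      a <- suppressWarnings(as.integer(x))
      fail_rows(is.na(a), cl, "non-integer age")
      out[[cl]] <- a
    } else if (cl %in% names(sc$categorical)) {
      v <- canonicalize_levels(x, sc$categorical[[cl]])
      fail_rows(is.na(v), cl, "unknown categorical level")
      out[[cl]] <- v
    } else if (cl == "nmb_agents") {
      parts <- decode_agents(x)
      canon <- lapply(parts, function(a) {
        canonicalize_levels(a, nmb_agent_set())
      })
      bad <- vapply(canon, anyNA, logical(1)) |
        vapply(canon, function(a) length(a) == 0, logical(1))
      fail_rows(bad & !is.na(x) & x != "", cl, "unknown NMB agent")
      out[[cl]] <- encode_agents(canon)
      out[[cl]][is.na(x) | x == ""] <- ""
    } else {
      b <- canonicalize_levels(x, c("TRUE", "FALSE"))
      fail_rows(is.na(b), cl, "non-logical flag")
      out[[cl]] <- b == "TRUE"
    }
  }
  out
}
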