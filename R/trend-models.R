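#' Default model covariate set with reference levels
#'
#' The ordered covariate list of the multivariable reversal-choice models:
#' NMB agent group (reference: one long-acting agent plus succinylcholine),
#' age band (reference 31-40), sex (reference male), race (reference White),
#' ethnicity (reference not Hispanic), admission type (reference elective),
#' low-income insurance, nine comorbidity flags, surgical type (reference
#' musculoskeletal/CNS), bed size (reference 400+), teaching status,
#' region (reference West), and COVID-19 history. Logical covariates use
#' reference `"FALSE"`.
#'
#' @return Named list: covariate name -> reference level.
#' @export
default_covariate_terms <- function() {
  cm <- c(
    "valvular_disease", "diabetes_complicated", "cardiac_arrhythmias",
    "sleep_apnea", "solid_tumor_without_metastasis",
    "peripheral_vascular_disorders", "obesity_overweight",
    "congestive_heart_failure", "chronic_pulmonary_disease"
  )
  c(
    list(
      nmb_group = "roc_or_vec_plus_succinylcholine",
      age_band = "31-40",
      sex = "male",
      race = "White",
      ethnicity = "not_hispanic",
      admission_type = "elective",
      low_income = "FALSE"
    ),
    stats::setNames(as.list(rep("FALSE", length(cm))), paste0("cm_", cm)),
    list(
      surgical_type = "msk_cns",
      bed_size = "400+",
      teaching = "FALSE",
      region = "West",
      covid_history = "FALSE"
    )
  )
}

#' Specify a reversal-choice trend model
#'
#' Defines one of the multivariable logistic models: the outcome contrast
#' (active vs spontaneous reversal, or sugammadex vs neostigmine among
#' actively reversed encounters), the covariate set with reference levels,
#' the continuous yearly time trend, and era-by-trend interaction terms for
#' the pandemic eras. Era main-effect dummies are excluded by default — the
#' pandemic eras enter only through their interaction with the time trend —
#' but can be switched on for sensitivity analysis.
#'
#' @param outcome `"active_vs_spontaneous"` (model of any pharmacologic
#'   reversal) or `"sugammadex_vs_neostigmine"` (agent choice given active
#'   reversal).
#' @param covariates Named list covariate -> reference level; default
#'   [default_covariate_terms()].
#' @param include_trend Include the continuous time covariate `t`.
#' @param era_interactions Subset of `c("EC", "MC", "LC")` receiving
#'   era-flag × trend interaction columns.
#' @param include_era_main_effects Also include era indicator dummies.
#' @param fit_window Two dates; rows outside are dropped before fitting.
#' @return An `nmb_model_spec`.
#' @export
model_spec <- function(outcome = c("active_vs_spontaneous",
                                   "sugammadex_vs_neostigmine"),
                       covariates = default_covariate_terms(),
                       include_trend = TRUE,
                       era_interactions = c("EC", "MC", "LC"),
                       include_era_main_effects = FALSE,
                       fit_window = as.Date(c("2018-01-01", "2021-12-31"))) {
  outcome <- match.arg(outcome)
  if (length(era_interactions) > 0) {
    era_interactions <- match.arg(era_interactions, covid_eras(),
                                  several.ok = TRUE)
  }
  structure(
    list(
      outcome = outcome,
      covariates = covariates,
      include_trend = isTRUE(include_trend),
      era_interactions = era_interactions,
      include_era_main_effects = isTRUE(include_era_main_effects),
      fit_window = as.Date(fit_window)
    ),
    class = "nmb_model_spec"
  )
}

covariate_values <- function(cohort, cov) {
  if (!cov %in% names(cohort)) {
    stop(sprintf("model covariate '%s' not present in cohort", cov),
         call. = FALSE)
  }
  as.character(cohort[[cov]])
}

canonical_covariate_levels <- function(cov, values) {
  lv <- nmb_levels()
  if (cov %in% names(lv)) return(lv[[cov]])
  if (all(values %in% c("TRUE", "FALSE"))) return(c("FALSE", "TRUE"))
  sort(unique(values))
}

## Dummy-code the spec covariates for `cohort`, returning the matrix columns
## and per-column metadata. `levels_map`, when supplied (prediction on new
## data), fixes the level sets seen at training time and turns unseen levels
## into an error rather than a silent reference fallback.
covariate_dummies <- function(cohort, covariates, levels_map = NULL) {
  cols <- list()
  meta <- list()
  map <- list()
  for (cov in names(covariates)) {
    ref <- as.character(covariates[[cov]])
    values <- covariate_values(cohort, cov)
    if (is.null(levels_map)) {
      canon <- canonical_covariate_levels(cov, values)
      levels <- intersect(canon, unique(values))
      if (!ref %in% levels) {
        stop(sprintf(
          "covariate '%s': reference level absent from data: %s", cov, ref
        ), call. = FALSE)
      }
    } else {
      levels <- levels_map[[cov]]
      unseen <- setdiff(unique(values), levels)
      if (length(unseen) > 0) {
        stop(sprintf(
          "covariate '%s' has level(s) unseen at training time: %s", cov,
          paste(unseen, collapse = ", ")
        ), call. = FALSE)
      }
    }
    if (!ref %in% levels) {
      stop(sprintf("reference level '%s' unknown for covariate '%s'", ref,
                   cov), call. = FALSE)
    }
    map[[cov]] <- levels
    for (l in setdiff(levels, ref)) {
      nm <- paste0(cov, "=", l)
      cols[[nm]] <- as.numeric(values == l)
      meta[[nm]] <- tibble::tibble(column = nm, covariate = cov, level = l)
    }
  }
  list(cols = cols, meta = dplyr::bind_rows(meta), levels_map = map)
}

## Structural (non-covariate) design columns: intercept, trend, era mains,
## era-by-trend interactions.
structural_columns <- function(cohort, spec) {
  cols <- list("(Intercept)" = rep(1, nrow(cohort)))
  t <- time_covariate(cohort$date)
  era <- as.character(assign_era(cohort$date))
  if (spec$include_trend) cols[["t"]] <- t
  if (spec$include_era_main_effects) {
    for (e in spec$era_interactions) {
      cols[[paste0("era_", e)]] <- as.numeric(era == e)
    }
  }
  for (e in spec$era_interactions) {
    cols[[paste0("t:era_", e)]] <- t * as.numeric(era == e)
  }
  cols
}

#' Build the design matrix and outcome vector for a trend model
#'
#' Applies the fit window, restricts to actively reversed encounters for the
#' sugammadex-vs-neostigmine contrast, dummy-codes the spec covariates
#' against their reference levels, and assembles the columns in reporting
#' order: intercept, time trend `t`, era-by-trend interactions
#' (`t:era_EC`, ...), then covariate dummies (`covariate=level`).
#'
#' @param cohort Analysis cohort from [build_cohort()].
#' @param spec An [model_spec()].
#' @return A list with `X` (numeric matrix), `y` (0/1 integer vector),
#'   `terms` (per-column metadata tibble), `levels_map` (training level sets
#'   per covariate), `n_obs`, and `spec`.
#' @export
build_design <- function(cohort, spec) {
  stopifnot(inherits(spec, "nmb_model_spec"))
  inside <- cohort$date >= spec$fit_window[1] &
    cohort$date <= spec$fit_window[2]
  data <- cohort[inside, , drop = FALSE]
  if (spec$outcome == "sugammadex_vs_neostigmine") {
    data <- data[data$reversal_class != "spontaneous", , drop = FALSE]
    y <- as.integer(data$reversal_class == "sugammadex")
  } else {
    y <- as.integer(data$reversal_class != "spontaneous")
  }
  if (length(unique(y)) < 2) {
    stop("degenerate outcome: only one outcome class present in the fit ",
         "window", call. = FALSE)
  }
  str_cols <- structural_columns(data, spec)
  dum <- covariate_dummies(data, spec$covariates)
  cols <- c(str_cols, dum$cols)
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, y = y, terms = dum$meta, levels_map = dum$levels_map,
       n_obs = nrow(X), spec = spec)
}

#' Maximum-likelihood logistic fit with Wald inference
#'
#' Fits a binary logistic regression by iteratively reweighted least squares
#' (via `stats::glm.fit`, relative deviance tolerance `1e-10`, at most 100
#' iterations) after verifying the design has full column rank. Standard
#' errors come from the inverse observed information; odds ratios, 95% Wald
#' confidence intervals (symmetric on the log scale) and two-sided Wald
#' p-values are reported per term. Rank deficiency, non-convergence, and
#' complete or quasi-complete separation (a fitted probability within 1e-10
#' of 0 or 1 alongside a diverging coefficient) are explicit errors, never
#' silent.
#'
#' @param X Numeric design matrix including an intercept column, or the list
#'   returned by [build_design()].
#' @param y 0/1 outcome vector (ignored when `X` is a design list).
#' @return An `nmb_trend_fit`: tibble `terms` (term, estimate, std_error,
#'   or, ci_low, ci_high, p_value), `coefficients`, `vcov`, `n_obs`,
#'   `log_lik`, `converged`, and (when fitted from a design list) the
#'   design metadata needed for prediction.
#' @examples
#' X <- cbind("(Intercept)" = 1, exposed = rep(c(1, 0), each = 100))
#' y <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
#' fit_logistic(X, y)$terms
#' @export
fit_logistic <- function(X, y = NULL) {
  design <- NULL
  if (is.list(X) && !is.null(X$X)) {
    design <- X
    y <- design$y
    X <- design$X
  }
  stopifnot(is.matrix(X), length(y) == nrow(X), all(y %in% c(0L, 1L)))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  # extreme fitted probabilities are diagnosed explicitly below, so glm's
  # own warning about them is redundant here
  fit <- withCallingHandlers(
    stats::glm.fit(
      x = X, y = y, family = stats::binomial(),
      control = stats::glm.control(epsilon = 1e-10, maxit = 100),
      intercept = FALSE
    ),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged) {
    stop("logistic fit did not converge within 100 IRLS iterations",
         call. = FALSE)
  }
  p <- fit$fitted.values
  beta <- fit$coefficients
  if (any(p < 1e-10 | p > 1 - 1e-10) && max(abs(beta)) > 15) {
    stop("separation detected: fitted probabilities at 0/1 with diverging ",
         "coefficients", call. = FALSE)
  }
  w <- p * (1 - p)
  info <- crossprod(X * sqrt(w))
  vcov <- chol2inv(chol(info))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))
  z <- beta / se
  terms <- tibble::tibble(
    term = colnames(X),
    estimate = unname(beta),
    std_error = unname(se),
    or = exp(unname(beta)),
    ci_low = exp(unname(beta - 1.96 * se)),
    ci_high = exp(unname(beta + 1.96 * se)),
    p_value = 2 * stats::pnorm(-abs(unname(z)))
  )
  structure(
    list(
      terms = terms,
      coefficients = beta,
      vcov = vcov,
      n_obs = nrow(X),
      log_lik = sum(y * log(p) + (1 - y) * log1p(-p)),
      converged = TRUE,
      levels_map = design$levels_map,
      spec = design$spec
    ),
    class = "nmb_trend_fit"
  )
}

#' Fit a reversal-choice trend model on a cohort
#'
#' Convenience wrapper: [build_design()] then [fit_logistic()], keeping the
#' spec and training level sets on the fit for later prediction.
#'
#' @param cohort Analysis cohort from [build_cohort()].
#' @param spec An [model_spec()].
#' @return An `nmb_trend_fit`.
#' @examples
#' ch <- build_cohort(generate_encounters(
#'   synthetic_config(n_encounters = 20000, seed = 5)))$cohort
#' sp <- model_spec("sugammadex_vs_neostigmine",
#'                  covariates = list(sex = "male"))
#' fit_trend_model(ch, sp)$terms[1:3, ]
#' @export
fit_trend_model <- function(cohort, spec) {
  fit_logistic(build_design(cohort, spec))
}

#' @export
print.nmb_trend_fit <- function(x, ...) {
  cat(sprintf("<nmb_trend_fit> n=%d, logLik=%.1f\n", x$n_obs, x$log_lik))
  print(x$terms, n = min(nrow(x$terms), 10))
  invisible(x)
}

#' Ordered odds-ratio report for a fitted trend model
#'
#' One row per model term (intercept omitted) in reporting order — time
#' trend, era-by-trend interactions, then covariates in spec order — with
#' the odds ratio, 95% Wald CI bounds, p-value, and a formatted
#' `"OR (low-high)"` string suitable for a forest plot or table.
#'
#' @param fit An `nmb_trend_fit`.
#' @param digits Decimal places in the formatted column (default 3).
#' @return A tibble: `term`, `or`, `ci_low`, `ci_high`, `p_value`,
#'   `or_ci`.
#' @export
report_fit <- function(fit, digits = 3) {
  stopifnot(inherits(fit, "nmb_trend_fit"))
  out <- fit$terms[fit$terms$term != "(Intercept)", ]
  fmt <- function(v) formatC(round(v, digits), format = "f", digits = digits)
  out$or_ci <- sprintf("%s (%s-%s)", fmt(out$or), fmt(out$ci_low),
                       fmt(out$ci_high))
  out[, c("term", "or", "ci_low", "ci_high", "p_value", "or_ci")]
}
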