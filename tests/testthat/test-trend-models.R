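test_that("design columns follow the date arithmetic and reference coding", {
  ch <- make_cohort(
    4,
    date = as.Date(c("2019-06-01", "2020-06-01", "2020-10-01",
                     "2021-06-01")),
    reversal_class = c("sugammadex", "neostigmine", "sugammadex",
                       "neostigmine"),
    admission_type = c("elective", "elective", "emergency", "urgent")
  )
  sp <- model_spec("sugammadex_vs_neostigmine",
                   covariates = list(admission_type = "elective"))
  d <- build_design(ch, sp)
  X <- d$X
  # pre-pandemic row: all interaction columns zero
  expect_equal(unname(X[1, c("t:era_EC", "t:era_MC", "t:era_LC")]),
               c(0, 0, 0))
  # EC row dated 2020-06-01: interaction equals t = 882/365.25
  expect_equal(unname(X[2, "t:era_EC"]), 882 / 365.25)
  expect_equal(unname(X[2, c("t:era_MC", "t:era_LC")]), c(0, 0))
  # elective is the reference: all admission dummies zero
  expect_equal(sum(X[1:2, grepl("admission_type", colnames(X))]), 0)
  expect_equal(unname(X[3, "admission_type=emergency"]), 1)
})

test_that("the sugammadex contrast restricts to actively reversed rows", {
  ch <- make_cohort(6, as.Date("2019-01-01"),
                    c("sugammadex", "neostigmine", "spontaneous",
                      "sugammadex", "neostigmine", "spontaneous"))
  sp <- model_spec("sugammadex_vs_neostigmine", covariates = list())
  d <- build_design(ch, sp)
  expect_equal(d$n_obs, 4)
  expect_equal(sort(unique(d$y)), c(0L, 1L))
})

test_that("degenerate outcomes and absent levels are explicit errors", {
  ch <- make_cohort(5, as.Date("2019-01-01"), "sugammadex")
  sp <- model_spec("sugammadex_vs_neostigmine", covariates = list())
  expect_error(build_design(ch, sp), "degenerate outcome")

  ch2 <- make_cohort(10, as.Date("2019-01-01"),
                     rep(c("sugammadex", "neostigmine"), 5),
                     sex = "female")
  sp2 <- model_spec("sugammadex_vs_neostigmine",
                    covariates = list(sex = "male"))
  expect_error(build_design(ch2, sp2), "absent from data.*male")
})

test_that("the logistic fit reproduces the closed-form 2x2 odds ratio", {
  X <- cbind("(Intercept)" = rep(1, 200),
             exposed = rep(c(1, 0), each = 100))
  y <- c(rep(1L, 30), rep(0L, 70), rep(1L, 10), rep(0L, 90))
  fit <- fit_logistic(X, y)
  or_hat <- fit$terms$or[fit$terms$term == "exposed"]
  expect_equal(or_hat, (30 * 90) / (70 * 10), tolerance = 1e-6)
  # Woolf-type Wald SE on the log OR
  expect_equal(fit$terms$std_error[2],
               sqrt(1 / 30 + 1 / 70 + 1 / 10 + 1 / 90), tolerance = 1e-6)

  balanced <- c(rep(1L, 50), rep(0L, 50), rep(1L, 50), rep(0L, 50))
  fit2 <- fit_logistic(X, balanced)
  expect_equal(fit2$terms$or[2], 1, tolerance = 1e-9)
})

test_that("Wald intervals are symmetric on the log scale and bracket the OR", {
  ch <- build_cohort(generate_encounters(recovery_config(20000, 77)))$cohort
  fit <- fit_trend_model(ch, recovery_spec())
  tt <- fit$terms
  expect_true(all(tt$ci_low < tt$or & tt$or < tt$ci_high))
  expect_true(all(tt$or > 0))
  expect_true(all(abs(tt$ci_low * tt$ci_high - tt$or^2) < 1e-9 * tt$or^2))
})

test_that("rank deficiency and separation are reported, never silent", {
  X <- cbind("(Intercept)" = rep(1, 40), a = rep(c(1, 0), 20),
             b = rep(c(1, 0), 20))
  y <- rep(c(1L, 0L), 20)
  expect_error(fit_logistic(X, y), "rank deficient.*b")

  Xs <- cbind("(Intercept)" = rep(1, 40), x = c(rep(1, 20), rep(0, 20)))
  ys <- c(rep(1L, 20), rep(0L, 20))
  expect_error(fit_logistic(Xs, ys), "separation")
})

test_that("shifting the time anchor leaves trend and interaction ORs fixed", {
  ch <- build_cohort(generate_encounters(recovery_config(15000, 55)))$cohort
  sp <- model_spec("sugammadex_vs_neostigmine",
                   covariates = list(sex = "male"),
                   include_era_main_effects = TRUE)
  d <- build_design(ch, sp)
  fit1 <- fit_logistic(d$X, d$y)
  delta <- 1.5
  X2 <- d$X
  for (e in c("EC", "MC", "LC")) {
    X2[, paste0("t:era_", e)] <- (d$X[, "t"] + delta) * d$X[, paste0("era_", e)]
  }
  X2[, "t"] <- d$X[, "t"] + delta
  fit2 <- fit_logistic(X2, d$y)
  keep <- c("t", "t:era_EC", "t:era_MC", "t:era_LC", "sex=female")
  expect_equal(fit1$coefficients[keep], fit2$coefficients[keep],
               tolerance = 1e-6)
  expect_false(isTRUE(all.equal(fit1$coefficients[["(Intercept)"]],
                                fit2$coefficients[["(Intercept)"]])))
})

test_that("dropping the interactions recovers the plain trend model", {
  ch <- build_cohort(generate_encounters(recovery_config(8000, 56)))$cohort
  sp0 <- model_spec("sugammadex_vs_neostigmine",
                    covariates = list(sex = "male"),
                    era_interactions = character(0))
  d0 <- build_design(ch, sp0)
  expect_false(any(grepl("era", colnames(d0$X))))
  f0 <- fit_logistic(d0)
  # hand-built design with the same columns gives the identical fit
  X <- cbind("(Intercept)" = 1, t = ch$t[ch$active],
             "sex=female" = as.numeric(ch$sex[ch$active] == "female"))
  f1 <- fit_logistic(X, as.integer(
    ch$reversal_class[ch$active] == "sugammadex"))
  expect_equal(unname(f0$coefficients), unname(f1$coefficients),
               tolerance = 1e-12)
})

test_that("estimates recover the generative coefficients at moderate n", {
  cfg <- recovery_config(60000, 500)
  ch <- build_cohort(generate_encounters(cfg))$cohort
  fit <- fit_trend_model(ch, recovery_spec())
  truth <- recovery_truth_1b(cfg)
  est <- fit$coefficients[names(truth)]
  expect_equal(unname(est["t"]), unname(truth["t"]), tolerance = 0.15)
  # every estimate within 5 SE of its generative value
  se <- fit$terms$std_error[match(names(truth), fit$terms$term)]
  expect_true(all(abs(est - truth) < 5 * se))
})

test_that("the report orders terms trend-first and formats printed ORs", {
  fit <- structure(list(terms = tibble::tibble(
    term = c("(Intercept)", "t"),
    estimate = c(0, log(1.129)),
    std_error = c(0.1, 0.0027),
    or = exp(estimate),
    ci_low = exp(estimate - 1.96 * std_error),
    ci_high = exp(estimate + 1.96 * std_error),
    p_value = c(1, 0)
  )), class = "nmb_trend_fit")
  rep <- report_fit(fit)
  expect_equal(rep$or_ci[rep$term == "t"], "1.129 (1.123-1.135)")

  ch <- build_cohort(generate_encounters(recovery_config(15000, 57)))$cohort
  full <- fit_trend_model(ch, recovery_spec())
  out <- report_fit(full)
  expect_equal(out$term[1:4], c("t", "t:era_EC", "t:era_MC", "t:era_LC"))
  expect_false("(Intercept)" %in% out$term)
  # zero-coefficient term formats as OR 1 with CI straddling 1
  fit0 <- structure(list(terms = tibble::tibble(
    term = "x", estimate = 0, std_error = 0.05, or = 1,
    ci_low = exp(-1.96 * 0.05), ci_high = exp(1.96 * 0.05), p_value = 1
  )), class = "nmb_trend_fit")
  r0 <- report_fit(fit0)
  expect_true(r0$ci_low < 1 && r0$ci_high > 1)
})
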