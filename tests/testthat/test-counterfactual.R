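test_that("the pre-pandemic model rejects post-window training rows", {
  ch <- make_cohort(10, as.Date(c(rep("2019-06-01", 9), "2020-04-15")),
                    rep(c("sugammadex", "neostigmine"), 5))
  expect_error(fit_counterfactual(ch, "2b", covariates = list()),
               "training window violation")
})

test_that("separable training data raises the fitter's separation error", {
  ch <- make_cohort(40, as.Date("2019-01-01") + rep(0:19, 2) * 7,
                    rep(c("sugammadex", "neostigmine"), each = 20),
                    sex = rep(c("female", "male"), each = 20))
  expect_error(
    fit_counterfactual(ch, "2b", covariates = list(sex = "male")),
    "separation"
  )
})

test_that("an all-zero coefficient vector predicts probability one half", {
  train <- make_cohort(40, as.Date("2019-01-01") + rep(0:19, 2) * 7,
                       rep(c("sugammadex", "neostigmine"), 20),
                       sex = rep(c("female", "male"), each = 20))
  m <- fit_counterfactual(train, "2b", covariates = list(sex = "male"))
  m$fit$coefficients[] <- 0
  covid <- make_cohort(5, as.Date("2020-06-01"), "sugammadex",
                       sex = "female")
  expect_equal(predict_covid_era(m, covid), rep(0.5, 5))
})

test_that("two encounters differing only in date differ only via the trend", {
  set.seed(88)
  train <- make_cohort(
    400, as.Date("2018-01-01") + sample(0:700, 400, replace = TRUE),
    sample(c("sugammadex", "neostigmine"), 400, replace = TRUE),
    sex = sample(c("female", "male"), 400, replace = TRUE)
  )
  m <- fit_counterfactual(train, "2b", covariates = list(sex = "male"))
  covid <- make_cohort(2, as.Date(c("2020-06-01", "2021-06-01")),
                       "sugammadex", sex = "female")
  p <- predict_covid_era(m, covid)
  beta_t <- m$fit$coefficients[["t"]]
  dt <- diff(time_covariate(covid$date))
  expect_equal(qlogis(p[2]) - qlogis(p[1]), beta_t * dt, tolerance = 1e-9)
})

test_that("prediction rejects out-of-era dates and unseen levels", {
  train <- make_cohort(40, as.Date("2019-01-01") + rep(0:19, 2) * 7,
                       rep(c("sugammadex", "neostigmine"), 20),
                       sex = rep(c("female", "male"), each = 20))
  m <- fit_counterfactual(train, "2b", covariates = list(sex = "male"))
  pre <- make_cohort(1, as.Date("2019-12-01"), "sugammadex", sex = "female")
  expect_error(predict_covid_era(m, pre), "outside the EC/MC/LC eras")

  # forge an unseen level in the pandemic rows
  covid <- make_cohort(2, as.Date("2020-06-01"), "sugammadex",
                       sex = c("female", "other"))
  expect_error(predict_covid_era(m, covid), "unseen at training time.*other")
})

test_that("AUROC matches the analytic AUROC of the generative logits", {
  cfg <- recovery_config(40000, 202)
  ch <- build_cohort(generate_encounters(cfg))$cohort
  win <- as.Date(c("2018-01-01", "2020-02-29"))
  train <- ch[ch$date <= win[2], ]
  m <- fit_counterfactual(train, "2b",
                          covariates = list(age_band = "31-40", sex = "male",
                                            admission_type = "elective"))
  # oracle: rank-based AUC of the true generative linear predictor
  act <- train[train$active, ]
  b <- cfg$beta_covariates$sug
  lp <- cfg$beta0_sug + cfg$beta_trend_sug * act$t +
    ifelse(is.na(b$age_band[as.character(act$age_band)]), 0,
           b$age_band[as.character(act$age_band)]) +
    ifelse(act$sex == "female", b$sex[["female"]], 0) +
    ifelse(is.na(b$admission_type[act$admission_type]), 0,
           b$admission_type[act$admission_type])
  y <- as.integer(act$reversal_class == "sugammadex")
  r <- rank(lp)
  auc_true <- (sum(r[y == 1]) - sum(y) * (sum(y) + 1) / 2) /
    (sum(y) * sum(1 - y))
  expect_lt(abs(m$auroc - auc_true), 0.01)
})

test_that("cutoff calibration is exact, ordered, and tie-stable", {
  cal <- calibrate_cutoff(c(0.9, 0.6, 0.4, 0.1), 2)
  expect_equal(cal$labels, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cal$cutoff, 0.6)

  # all ties: exactly k positives, broken by ascending id
  tie <- calibrate_cutoff(rep(0.5, 5), 3, ids = c("e", "d", "c", "b", "a"))
  expect_equal(sum(tie$labels), 3)
  expect_equal(which(tie$labels), c(3, 4, 5)) # ids a, b, c

  none <- calibrate_cutoff(c(0.2, 0.8), 0)
  expect_equal(sum(none$labels), 0)
  expect_gt(none$cutoff, 0.8)

  expect_error(calibrate_cutoff(c(0.5, 0.5), 3), "must lie in")
})

test_that("calibrated counts equal the request for arbitrary vectors", {
  set.seed(321)
  for (i in 1:25) {
    n <- sample(1:60, 1)
    p <- sample(c(stats::runif(n), rep(0.5, n)), n)
    k <- sample(0:n, 1)
    cal <- calibrate_cutoff(p, k)
    expect_equal(sum(cal$labels), k)
  }
})

test_that("identical label sets give unit ratios everywhere", {
  set.seed(5)
  ch <- make_cohort(300, as.Date("2021-06-01"),
                    sample(c("sugammadex", "neostigmine"), 300,
                           replace = TRUE),
                    sex = sample(c("female", "male"), 300, replace = TRUE))
  lab <- ch$reversal_class == "sugammadex"
  tab <- counterfactual_or_table(ch, lab, lab, "sex", eras = "LC")
  expect_true(all(tab$ratio == 1))
  expect_true(all(tab$normalized_ratio == 1))
})

test_that("Woolf intervals match the closed-form contingency oracle", {
  ch <- make_cohort(100, as.Date("2020-06-01"), "sugammadex", sex = "female")
  actual <- c(rep(TRUE, 30), rep(FALSE, 70))
  counter <- c(rep(TRUE, 10), rep(FALSE, 90))
  tab <- counterfactual_or_table(ch, actual, counter, "sex", eras = "EC")
  row <- tab[tab$level == "female", ]
  ratio <- (30 / 70) / (10 / 90)
  se <- sqrt(1 / 30 + 1 / 70 + 1 / 10 + 1 / 90)
  expect_equal(row$ratio, ratio, tolerance = 1e-12)
  # the overall row is the same 2x2 here, so the scaling factor is 1/ratio
  expect_equal(row$normalized_ratio, 1, tolerance = 1e-12)
  expect_equal(row$ci_low, exp(log(ratio) - 1.96 * se) / ratio,
               tolerance = 1e-12)
  expect_equal(row$ci_high, exp(log(ratio) + 1.96 * se) / ratio,
               tolerance = 1e-12)
})

test_that("zero cells get the continuity correction and a flag", {
  ch <- make_cohort(20, as.Date("2020-06-01"), "sugammadex",
                    sex = rep(c("female", "male"), each = 10))
  actual <- rep(c(TRUE, FALSE), 10)
  counter <- c(rep(TRUE, 5), rep(FALSE, 15)) # males: zero cf positives
  tab <- counterfactual_or_table(ch, actual, counter, "sex", eras = "EC")
  male <- tab[tab$level == "male", ]
  expect_true(male$corrected)
  expect_equal(male$or_counterfactual, 0.5 / 10.5, tolerance = 1e-12)
  female <- tab[tab$level == "female", ]
  expect_false(female$corrected)
})

test_that("normalization identities hold for both variants", {
  set.seed(31)
  n <- 2000
  ch <- make_cohort(
    n, as.Date("2020-04-01") + sample(0:600, n, replace = TRUE),
    sample(c("sugammadex", "neostigmine"), n, replace = TRUE),
    sex = sample(c("female", "male"), n, replace = TRUE),
    bed_size = sample(c("0-199", "200-399", "400+"), n, replace = TRUE)
  )
  ch <- ch[as.character(ch$era) %in% c("EC", "MC", "LC"), ]
  actual <- stats::runif(nrow(ch)) < 0.55
  counter <- stats::runif(nrow(ch)) < 0.50

  tab <- counterfactual_or_table(ch, actual, counter, c("sex", "bed_size"))
  overall <- tab[tab$covariate == "(all)", ]
  expect_true(all(abs(overall$normalized_ratio - 1) < 1e-12))

  geo <- counterfactual_or_table(ch, actual, counter, c("sex", "bed_size"),
                                 normalization = "geomean")
  lev <- geo[geo$covariate != "(all)", ]
  gm <- tapply(lev$n * log(lev$normalized_ratio),
               paste(lev$era, lev$covariate),
               sum) / tapply(lev$n, paste(lev$era, lev$covariate), sum)
  expect_true(all(abs(gm) < 1e-9))
})

test_that("model-expected counterfactual counts are null-faithful", {
  # no era shock: expected-count comparison should flag (almost) nothing
  cfg <- synthetic_config(
    n_encounters = 120000, seed = 71,
    era_interaction = list(active = c(EC = 0, MC = 0, LC = 0),
                           sug = c(EC = 0, MC = 0, LC = 0))
  )
  ch <- build_cohort(generate_encounters(cfg))$cohort
  res <- run_counterfactual(ch, "2b", label_method = "expected")
  tab <- res$table[res$table$covariate != "(all)", ]
  cover <- tab$ci_low <= 1 & tab$ci_high >= 1
  expect_gte(mean(cover), 0.90)
})
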