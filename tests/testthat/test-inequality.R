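test_that("the reference level is the earliest-initiating level", {
  tb <- mini_cohort(60,
                    education = rep(c("high", "medium", "low"), each = 20),
                    init_weeks = rep(c(12, 10, 12), each = 20))
  expect_identical(choose_reference(tb, "education"), "medium")

  # ties break by dictionary order
  tb2 <- mini_cohort(40,
                     employment = rep(c("yes", "no"), each = 20),
                     init_weeks = rep(11, 40))
  expect_identical(choose_reference(tb2, "employment"), "yes")

  # empty levels are excluded with a warning
  tb3 <- mini_cohort(40,
                     education = rep(c("high", "low"), each = 20),
                     init_weeks = rep(c(12, 10), each = 20))
  expect_warning(ref <- choose_reference(tb3, "education"), "medium")
  expect_identical(ref, "low")

  # idempotence
  expect_identical(choose_reference(tb, "education"),
                   choose_reference(tb, "education"))
})

test_that("single-predictor OLS contrasts equal group-mean differences exactly", {
  tb <- mini_cohort(50,
                    employment = rep(c("no", "yes"), times = c(20, 30)),
                    init_weeks = rep(c(14, 12), times = c(20, 30)))
  fit <- estimate_inequality(tb, "employment", reference = "yes")
  expect_equal(unname(fit$coefs["employmentno"]), 2.0, tolerance = 1e-10)

  # equal group means produce null contrasts
  tb0 <- mini_cohort(30, education = rep(c("high", "medium", "low"), 10),
                     init_weeks = rep(9, 30))
  fit0 <- estimate_inequality(tb0, "education", reference = "high")
  expect_equal(max(abs(fit0$coefs[-1])), 0, tolerance = 1e-12)

  # property: random tables, every contrast equals the mean difference
  set.seed(55)
  for (i in 1:25) {
    n <- sample(30:120, 1)
    g <- sample(c("low", "medium", "high"), n, replace = TRUE)
    y <- rnorm(n, mean = 10 + 2 * (g == "low"))
    tb <- mini_cohort(n, deprivation = g, init_weeks = y)
    ref <- choose_reference(tb, "deprivation")
    fit <- estimate_inequality(tb, "deprivation", ref)
    mns <- tapply(y, g, mean)
    for (l in setdiff(unique(g), ref)) {
      expect_equal(unname(fit$coefs[paste0("deprivation", l)]),
                   unname(mns[l] - mns[ref]), tolerance = 1e-10)
    }
  }
})

test_that("the adjusted model recovers the generating exposure effect", {
  p <- default_params(50000)
  cohort <- generate_cohort(p, seed = 19)
  fit <- fit_adjusted_exposure_model(cohort)
  se <- sqrt(fit$vcov["early_recognition", "early_recognition"])
  expect_lt(abs(fit$exposure_beta - (-0.6)), 3 * se)

  # a generating outcome coefficient is recovered by its unadjusted contrast
  # when the exposure is independent of the covariates
  p0 <- unconfounded_params(50000)
  cohort0 <- generate_cohort(p0, seed = 20)
  ineq <- estimate_inequality(cohort0, "education", reference = "high")
  se_l <- sqrt(ineq$vcov["educationlow", "educationlow"])
  expect_lt(abs(ineq$coefs[["educationlow"]] - 1.5), 3 * se_l)

  # without confounding, adjusted and unadjusted exposure effects agree
  fit0 <- fit_adjusted_exposure_model(cohort0)
  unadj <- lm(init_weeks ~ early_recognition, data = cohort0)
  se_cmp <- sqrt(vcov(unadj)[2, 2])
  expect_lt(abs(fit0$exposure_beta - coef(unadj)[[2]]), 3 * se_cmp)
})

test_that("a null exposure effect is estimated near zero", {
  p <- default_params(20000)
  p$exposure_effect <- 0
  p <- calibrate_params(p)
  cohort <- generate_cohort(p, seed = 23)
  fit <- fit_adjusted_exposure_model(cohort)
  se <- sqrt(fit$vcov["early_recognition", "early_recognition"])
  expect_lt(abs(fit$exposure_beta), 3 * se)
})

test_that("tidy and glance expose the fit in broom shape", {
  cohort <- generate_cohort(default_params(1500), seed = 2)
  fit <- fit_adjusted_exposure_model(cohort)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error", "conf_low", "conf_high")
                  %in% names(td)))
  expect_true("early_recognition" %in% td$term)
  expect_true(all(td$conf_low <= td$estimate & td$estimate <= td$conf_high))
  gl <- glance(fit)
  expect_equal(gl$n, 1500)
})
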