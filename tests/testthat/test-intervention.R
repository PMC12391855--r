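shift_fit <- function(beta) {
  structure(list(exposure_beta = beta), class = "ineq_fit")
}

test_that("counterfactual outcomes shift only the unexposed", {
  tb <- mini_cohort(3,
                    recognition_weeks = c(10, 4, 10),
                    init_weeks = c(14, 11, 13))
  ystar <- counterfactual_outcomes(tb, shift_fit(-0.6))
  expect_equal(ystar, c(13.4, 11, 12.4))          # A=0 shifted by -0.6
  expect_equal(counterfactual_outcomes(tb, shift_fit(0)), tb$init_weeks)

  # consistency on a full synthetic cohort with an estimated effect
  cohort <- generate_cohort(default_params(2000), seed = 6)
  fit <- fit_adjusted_exposure_model(cohort)
  ys <- counterfactual_outcomes(cohort, fit)
  exposed <- cohort$early_recognition == 1
  expect_identical(ys[exposed], cohort$init_weeks[exposed])
  # and the predict route coincides with the shift for a main-effects model
  ys2 <- counterfactual_outcomes(cohort, fit, method = "predict")
  expect_equal(ys, ys2, tolerance = 1e-10)
})

test_that("reductions obey the closed-form prevalence-gap identity", {
  cohort <- generate_cohort(default_params(), seed = 13)
  fit <- fit_adjusted_exposure_model(cohort)
  for (pred in c("education", "age_group", "housing")) {
    ref <- choose_reference(cohort, pred)
    red <- estimate_reduction(cohort, pred, fit, reference = ref)
    abar <- tapply(cohort$early_recognition, cohort[[pred]], mean)
    expected <- fit$exposure_beta * (abar[[ref]] - as.numeric(abar[red$level]))
    expect_equal(red$reduction, expected, tolerance = 1e-10)
    # reference row is exactly zero
    expect_equal(red$beta_without[red$is_reference], 0)
    expect_equal(red$reduction[red$is_reference], 0)
  }
})

test_that("equal exposure prevalence or a null effect produce zero reduction", {
  tb <- mini_cohort(80,
                    housing = rep(c("own", "rented"), 40),
                    recognition_weeks = rep(c(4, 10), each = 40),
                    init_weeks = rnorm(80, 12))
  # A is balanced across housing levels by construction
  red <- estimate_reduction(tb, "housing", shift_fit(-1), reference = "own")
  expect_equal(red$reduction, c(0, 0), tolerance = 1e-10)

  cohort <- generate_cohort(default_params(1500), seed = 3)
  red0 <- estimate_reduction(cohort, "income", shift_fit(0), reference = "high")
  expect_equal(red0$reduction, rep(0, 3), tolerance = 1e-12)
})

test_that("a negative effect with lower exposure in the disadvantaged level shrinks the gap", {
  cohort <- generate_cohort(default_params(20000), seed = 17)
  fit <- fit_adjusted_exposure_model(cohort)
  red <- estimate_reduction(cohort, "education", fit, reference = "high")
  expect_lt(red$reduction[red$level == "low"], 0)
})

test_that("the standardisation oracle reproduces a hand-worked example", {
  # stratum a: exposed outcomes 10, 10; unexposed 13 -> counterfactual 10
  # stratum b: exposed 12, 12; unexposed 15, 15 -> counterfactual 12
  # observed means: a = 11, b = 13.5; counterfactual means: a = 10, b = 12
  tb <- tibble::tibble(
    housing = factor(c("own", "own", "own", "rented", "rented", "rented", "rented"),
                     levels = c("own", "rented")),
    early_recognition = c(1, 1, 0, 1, 1, 0, 0),
    init_weeks = c(10, 10, 13, 12, 12, 15, 15))
  orc <- standardization_oracle(tb, "housing")
  expect_identical(orc$level[orc$is_reference], "own")
  expect_equal(orc$beta_without[orc$level == "rented"], 2.5)
  expect_equal(orc$beta_with[orc$level == "rented"], 2.0)
  expect_equal(orc$reduction[orc$level == "rented"], -0.5)
})

test_that("the oracle is the identity when everyone is already exposed", {
  tb <- mini_cohort(40,
                    education = rep(c("high", "low"), 20),
                    recognition_weeks = rep(3, 40),
                    init_weeks = rnorm(40, 12))
  orc <- standardization_oracle(tb, "education")
  expect_equal(orc$beta_with, orc$beta_without)
  expect_equal(orc$reduction, rep(0, nrow(orc)))
})

test_that("the oracle rejects strata that violate positivity", {
  tb <- tibble::tibble(
    housing = factor(rep(c("own", "rented"), each = 4),
                     levels = c("own", "rented")),
    early_recognition = c(1, 1, 0, 0, 0, 0, 0, 0),
    init_weeks = rnorm(8, 12))
  expect_error(standardization_oracle(tb, "housing"),
               "positivity", class = "ineqshift_positivity_error")
})

test_that("g-computation with a saturated model matches the oracle", {
  for (s in 1:20) {
    tb <- random_saturated_table(seed = 300 + s)
    sat <- fit_adjusted_exposure_model(tb, predictors = "employment",
                                       interactions = TRUE)
    red <- estimate_reduction(tb, "employment", sat, method = "predict")
    orc <- standardization_oracle(tb, "employment")
    expect_equal(red$reduction[match(orc$level, red$level)], orc$reduction,
                 tolerance = 1e-10)
  }
})
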