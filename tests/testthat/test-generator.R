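test_that("default parameters reproduce the published marginals and rates", {
  p <- default_params()
  counts <- calibration_counts()

  expect_equal(p$exposure_effect, -0.6)
  expect_equal(p$exposure_model$target_prevalence, 0.817)
  expect_equal(p$missing_rates[["recognition_weeks"]], 0.255, tolerance = 1e-3)

  # prevalences match the printed proportions (0.5 percentage points)
  for (v in setdiff(predictor_names(), "parity")) {
    tb <- counts[counts$variable == v, ]
    printed <- tb$total / sum(tb$total)
    expect_equal(unname(p$prevalences[[v]][tb$level]), printed,
                 tolerance = 0.005, label = v)
    expect_equal(sum(p$prevalences[[v]]), 1, tolerance = 1e-12)
  }
  expect_equal(p$regular_cycle_prevalence, 0.562, tolerance = 0.005)

  # predictor missingness spans 1.1% to 36.2%
  pred_rates <- p$missing_rates[intersect(names(p$missing_rates), predictor_names())]
  expect_lt(abs(min(pred_rates) - 0.011), 0.001)
  expect_lt(abs(max(pred_rates) - 0.362), 0.001)
})

test_that("parameter validation names the offending field", {
  p <- default_params(100)
  p$prevalences$education <- c(high = 0.5, medium = 0.4, low = 0.2)
  expect_error(validate_params(p), "prevalences\\$education")

  p2 <- default_params(100)
  p2$missing_rates["init_weeks"] <- 0.1
  expect_error(validate_params(p2), "init_weeks",
               class = "ineqshift_parameter_error")

  p3 <- default_params(100)
  p3$noise_sd <- -1
  expect_error(validate_params(p3), "noise_sd")
})

test_that("a noiseless flat outcome model produces a constant outcome", {
  p <- degenerate_params(200, intercept = 12)
  cohort <- generate_cohort(p, seed = 1)
  expect_equal(cohort$init_weeks, rep(12, 200), tolerance = 1e-6)
})

test_that("the same seed reproduces the cohort exactly", {
  p <- default_params(500)
  expect_identical(generate_cohort(p, seed = 31), generate_cohort(p, seed = 31))
  expect_false(identical(generate_cohort(p, seed = 31),
                         generate_cohort(p, seed = 32)))
})

test_that("generated marginals match the calibration targets within 3 binomial SEs", {
  p <- default_params()
  cohort <- generate_cohort(p, seed = 42)
  n <- nrow(cohort)

  for (v in setdiff(predictor_names(), "parity")) {
    target <- p$prevalences[[v]]
    observed <- prop.table(table(cohort[[v]]))
    for (l in names(target)) {
      se <- sqrt(target[[l]] * (1 - target[[l]]) / n)
      expect_lt(abs(observed[[l]] - target[[l]]), 3 * se,
                label = paste(v, l))
    }
  }
  se_a <- sqrt(0.817 * 0.183 / n)
  expect_lt(abs(mean(cohort$early_recognition) - 0.817), 3 * se_a)
  se_c <- sqrt(0.562 * 0.438 / n)
  expect_lt(abs(mean(cohort$regular_cycle) - 0.562), 3 * se_c)
})

test_that("outcome and recognition moments match the published values", {
  p <- default_params(20000)
  cohort <- generate_cohort(p, seed = 7)
  expect_equal(mean(cohort$init_weeks), 12.9, tolerance = 0.01)   # relative
  expect_equal(sd(cohort$init_weeks), 3.7, tolerance = 0.02)
  expect_equal(mean(cohort$recognition_weeks), 5.4, tolerance = 0.02)
  expect_equal(sd(cohort$recognition_weeks), 2.3, tolerance = 0.07)
  # recognition consistent with the exposure by construction
  expect_identical(cohort$early_recognition,
                   as.integer(cohort$recognition_weeks <= 6))
  expect_true(all(cohort$init_weeks >= 4))
})

test_that("exposure probabilities stay inside (0, 1) in every stratum", {
  p <- default_params()
  joint <- ineqshift:::.exposure_joint(p)
  probs <- plogis(p$exposure_model$intercept + joint$lp)
  expect_true(all(probs > 0.2 & probs < 0.99))
})

test_that("missingness hits its per-variable rates and never touches the outcome", {
  p <- default_params(10000)
  cohort <- generate_cohort(p, seed = 11)
  blanked <- apply_missingness(cohort, p, seed = 12)

  expect_false(anyNA(blanked$init_weeks))
  for (v in names(p$missing_rates)) {
    r <- p$missing_rates[[v]]
    if (r == 0) next
    realised <- mean(is.na(blanked[[v]]))
    se <- sqrt(r * (1 - r) / nrow(cohort))
    expect_lt(abs(realised - r), 3 * se, label = v)
  }
  # the published recognition rate lands in its 3-SE band at n = 10000
  expect_gt(mean(is.na(blanked$recognition_weeks)), 0.242)
  expect_lt(mean(is.na(blanked$recognition_weeks)), 0.268)
  # derived indicator blanked with its source
  expect_identical(is.na(blanked$early_recognition),
                   is.na(blanked$recognition_weeks))
})

test_that("zero missing rates leave the table untouched", {
  p <- default_params(300)
  p$missing_rates[] <- 0
  cohort <- generate_cohort(p, seed = 2)
  expect_identical(apply_missingness(cohort, p, seed = 3), cohort)
})
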