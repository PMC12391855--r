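test_that("a table with no missing cells returns m identical copies", {
  p <- default_params(150)
  cohort <- generate_cohort(p, seed = 5)
  imp <- impute_chained(cohort, m = 3, iterations = 2, seed = 1)
  expect_length(imp$tables, 3)
  for (tb in imp$tables) expect_identical(tb, cohort)
  expect_identical(imp$visit_order, character(0))
})

test_that("imputation preserves observed cells, fills all gaps, and keeps invariants", {
  p <- default_params(800)
  cohort <- generate_cohort(p, seed = 8)
  obs <- apply_missingness(cohort, p, seed = 9)
  imp <- impute_chained(obs, m = 2, iterations = 2, seed = 10)

  for (tb in imp$tables) {
    expect_false(anyNA(tb[setdiff(names(tb), "participant_id")]))
    for (v in names(obs)) {
      seen <- !is.na(obs[[v]])
      expect_identical(as.character(obs[[v]][seen]), as.character(tb[[v]][seen]),
                       info = v)
    }
    # PMM: every imputed continuous value is an observed donor value,
    # hence inside the observed range
    for (v in c("recognition_weeks", "bmi_intake", "ga_intake", "apgar5")) {
      mis <- is.na(obs[[v]])
      expect_true(all(tb[[v]][mis] %in% obs[[v]][!mis]), info = v)
    }
    # passive imputation keeps the derived indicator consistent
    expect_identical(tb$early_recognition,
                     as.integer(tb$recognition_weeks <= 6))
  }
  # visit order is ascending missing fraction
  fr <- vapply(imp$visit_order, function(v) mean(is.na(obs[[v]])), numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("imputation is reproducible from its seed", {
  p <- default_params(400)
  obs <- apply_missingness(generate_cohort(p, seed = 3), p, seed = 4)
  a <- impute_chained(obs, m = 2, iterations = 2, seed = 77)
  b <- impute_chained(obs, m = 2, iterations = 2, seed = 77)
  expect_identical(a$tables, b$tables)
})

test_that("a fully missing variable is rejected", {
  tb <- mini_cohort(50)
  tb$iq <- factor(NA_character_, levels = cohort_levels()$iq)
  expect_error(impute_chained(tb, m = 2, iterations = 1, seed = 1),
               "no observed values", class = "ineqshift_unimputable_error")
})

test_that("the in-package multinomial fitter agrees with nnet", {
  skip_if_not_installed("nnet")
  set.seed(21)
  n <- 800
  x1 <- rnorm(n); x2 <- rnorm(n)
  eta2 <- 0.5 + 0.8 * x1 - 0.4 * x2
  eta3 <- -0.3 + 0.2 * x1 + 0.6 * x2
  den <- 1 + exp(eta2) + exp(eta3)
  u <- runif(n)
  y <- 1L + (u > 1 / den) + (u > (1 + exp(eta2)) / den)
  X <- cbind(1, x1, x2)
  fit <- ineqshift:::.multinom_draw(X, y, K = 3, Xm = X[1:2, , drop = FALSE])
  ref <- nnet::multinom(factor(y) ~ x1 + x2, trace = FALSE)
  expect_equal(unname(t(fit$B)), unname(coef(ref)), tolerance = 1e-3)
})

test_that("Rubin pooling follows the combining rules", {
  p1 <- pool_rubin(c(1, 1, 1), c(4, 4, 4))
  expect_equal(p1$estimate, 1)
  expect_equal(p1$within_var, 4)
  expect_equal(p1$between_var, 0)
  expect_equal(p1$total_var, 4)

  p2 <- pool_rubin(c(0, 2), c(1, 1))
  expect_equal(p2$estimate, 1)
  expect_equal(p2$between_var, 2)
  expect_equal(p2$total_var, 1 + (1 + 1 / 2) * 2)
  expect_true(p2$ci[1] <= p2$estimate && p2$estimate <= p2$ci[2])

  expect_error(pool_rubin(1, 1), "m >= 2")
  expect_error(pool_rubin(c(1, 2), c(1, -1)), "non-negative")

  # invariant holds for arbitrary inputs
  set.seed(99)
  for (i in 1:20) {
    est <- rnorm(7); vr <- rchisq(7, 3)
    pp <- pool_rubin(est, vr)
    expect_equal(pp$total_var, pp$within_var + (1 + 1 / 7) * pp$between_var,
                 tolerance = 1e-12)
  }
})

test_that("pooled prevalence after MAR blanking tracks the complete-data value", {
  p <- default_params(2000)
  cohort <- generate_cohort(p, seed = 14)
  obs <- apply_missingness(cohort, p, seed = 15)
  imp <- impute_chained(obs, m = 5, iterations = 2, seed = 16)

  prev <- vapply(imp$tables, function(tb) mean(tb$early_recognition), numeric(1))
  vr <- prev * (1 - prev) / nrow(cohort)
  pooled <- pool_rubin(prev, vr)
  truth <- mean(cohort$early_recognition)
  expect_lt(abs(pooled$estimate - truth), 3 * sqrt(pooled$total_var))
})
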