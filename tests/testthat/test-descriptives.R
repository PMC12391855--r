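test_that("the 6-week dichotomisation is inclusive and propagates missingness", {
  expect_identical(dichotomize_early(c(5, 6, 6.1, NA)), c(1L, 1L, 0L, NA))
  expect_error(dichotomize_early(-1), "non-negative",
               class = "ineqshift_domain_error")
})

test_that("the 14-week dichotomisation is inclusive and rejects missing outcomes", {
  expect_identical(dichotomize_timely(c(12.9, 14, 15)), c(1L, 1L, 0L))
  expect_error(dichotomize_timely(c(12, NA)), "missing",
               class = "ineqshift_domain_error")
  expect_error(dichotomize_timely(0), "positive")
})

test_that("the descriptive table conserves counts and percentages", {
  p <- default_params(3000)
  obs <- apply_missingness(generate_cohort(p, seed = 25), p, seed = 26)
  t1 <- make_table1(obs)

  # timely + late = total for every level, even with missingness
  expect_equal(t1$n_timely + t1$n_late, t1$n_total)
  # percentages per variable per stratum sum to 100 (rounding tolerance)
  sums <- tapply(t1$pct_total, t1$variable, sum)
  expect_true(all(abs(sums - 100) <= 0.11))
  # a variable with no missing cells accounts for every participant
  cyc <- t1[t1$variable == "regular_cycle", ]
  expect_equal(sum(cyc$n_total), nrow(obs))
  expect_equal(sum(cyc$n_timely), sum(dichotomize_timely(obs$init_weeks)))
})

test_that("descriptive percentages reproduce a known composition", {
  # 2554 early of 3126 respondents (81.7%), everyone timely
  tb <- mini_cohort(3126,
                    recognition_weeks = rep(c(4, 10), times = c(2554, 572)))
  t1 <- make_table1(tb)
  early <- t1[t1$variable == "early_recognition", ]
  expect_equal(early$pct_total[early$level == "yes"], 81.7)
  expect_equal(early$pct_total[early$level == "no"], 18.3)
})

test_that("the propensity model recovers a covariate-free exposure", {
  p <- unconfounded_params(5000, prevalence = 0.8)
  cohort <- generate_cohort(p, seed = 27)
  rep <- check_positivity(cohort)
  expect_equal(rep$n, 5000)
  # with no true gradients the mean fitted equals the sample prevalence,
  # and no stratum strays far from it
  se <- sqrt(0.8 * 0.2 / 5000)
  expect_lt(abs(mean(rep$probabilities) - 0.8), 3 * se)
  expect_gt(rep$minimum, 0.5)
  expect_true(all(rep$probabilities > 0 & rep$probabilities < 1))
})

test_that("the default generator keeps propensities far from zero", {
  cohort <- generate_cohort(default_params(), seed = 28)
  rep <- check_positivity(cohort)
  expect_gt(rep$minimum, 0.05)
})

test_that("perfect separation is reported with the offending covariate", {
  tb <- mini_cohort(60,
                    housing = rep(c("own", "rented"), each = 30),
                    recognition_weeks = c(rep(4, 30), rep(c(4, 10), 15)))
  # every 'own' row is exposed
  expect_error(check_positivity(tb), "housing",
               class = "ineqshift_separation_error")
})

test_that("a propensity floor breach warns", {
  p <- default_params(4000)
  cohort <- generate_cohort(p, seed = 29)
  expect_warning(check_positivity(cohort, floor = 0.99), "floor")
})

test_that("the regular-cycle filter keeps exactly the regular rows", {
  tb <- mini_cohort(10, regular_cycle = rep(c(1L, 0L), 5))
  out <- filter_regular_cycle(tb)
  expect_equal(nrow(out), 5)
  expect_true(all(out$regular_cycle == 1))
  expect_identical(filter_regular_cycle(out), out)

  none <- mini_cohort(4, regular_cycle = rep(0L, 4))
  expect_error(filter_regular_cycle(none), "regular cycle")
  expect_error(filter_regular_cycle(tb[setdiff(names(tb), "regular_cycle")]),
               "regular_cycle", class = "ineqshift_column_error")
})
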