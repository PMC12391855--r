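#' Default synthetic-cohort generator parameters
#'
#' Returns the full set of distributional knobs of the synthetic cohort,
#' calibrated so that a generated cohort reproduces the published marginals of
#' the analytical sample it emulates: predictor prevalences and per-variable
#' missingness rates derived from [calibration_counts()], an early-recognition
#' prevalence of 0.817, an outcome mean of 12.9 weeks with SD 3.7, a
#' recognition-timing mean of 5.4 weeks with SD 2.3, and a true adjusted
#' exposure effect of -0.6 weeks.
#'
#' The exposure model is a logistic linear predictor on education, household
#' income, age group and pregnancy intention — the steepest published
#' gradients — whose intercept is solved numerically so the implied marginal
#' prevalence of early recognition equals `0.817` while every covariate
#' stratum keeps an exposure probability strictly inside (0, 1) (positivity by
#' construction). The outcome intercept and the residual SD are likewise
#' solved so the implied marginal outcome moments match 12.9 and 3.7 weeks,
#' accounting for the exposure-covariate dependence.
#'
#' @param n Cohort size; defaults to the analytical sample size 4196.
#' @return An object of class `cohort_params`: a named list with fields
#'   `n`, `prevalences`, `exposure_model`, `outcome_intercept`,
#'   `outcome_coefs`, `exposure_effect`, `noise_sd`, `missing_rates`,
#'   `mar_dependence` and `seed`.
#' @seealso [generate_cohort()], [apply_missingness()]
#' @export
#' @examples
#' p <- default_params()
#' p$exposure_effect            # -0.6 weeks
#' p$missing_rates[["recognition_weeks"]]
default_params <- function(n = 4196L) {
  counts <- calibration_counts()
  tabled <- split(counts, counts$variable)

  prevalences <- lapply(predictor_names(), function(v) {
    if (v == "parity") {
      # parity marginals were not published; plausible primiparous-majority mix
      return(c("0" = 0.55, "1" = 0.30, "2" = 0.10, ">=3" = 0.05))
    }
    tb <- tabled[[v]]
    setNames(tb$total / sum(tb$total), tb$level)[.predictor_levels[[v]]]
  })
  names(prevalences) <- predictor_names()

  # inequality coefficients (weeks vs the earliest-initiating level) follow
  # the published without-intervention contrasts, so that the empirical
  # reference rule recovers the published reference levels
  outcome_coefs <- list(
    age_group      = c("<20" = 3.0, "20-25" = 1.0, "25-30" = 0.3,
                       "30-35" = 0.0, ">=35" = 0.7),
    migration      = c(none = 0.0, "2nd_generation" = 1.0,
                       "1st_generation" = 1.5),
    relationship   = c(partner = 0.0, single = 1.4),
    intention      = c(planned = 0.0, unplanned_wanted = 1.1,
                       unplanned_ambivalent = 2.1),
    mental_illness = c(no = 0.3, ever = 0.0, recent = 0.4),
    language       = c(sufficient = 0.0, reasonable = 0.7,
                       insufficient = 1.3),
    parity         = c("0" = 0.0, "1" = 0.1, "2" = 0.8, ">=3" = 1.6),
    education      = c(high = 0.0, medium = 0.4, low = 1.5),
    employment     = c(yes = 0.0, no = 1.6),
    income         = c(high = 0.0, medium = 0.9, low = 2.1),
    housing        = c(own = 0.0, rented = 1.2),
    deprivation    = c(low = 0.0, medium = 0.7, high = 1.5),
    iq             = c(">=85" = 0.0, "70-85" = 0.8, "<70" = 1.4)
  )

  exposure_model <- list(
    target_prevalence = 0.817,
    coefs = list(
      education = c(high = 0, medium = -0.25, low = -0.5),
      income    = c(high = 0, medium = -0.2, low = -0.4),
      age_group = c("<20" = -0.5, "20-25" = -0.25, "25-30" = -0.05,
                    "30-35" = 0, ">=35" = -0.1),
      intention = c(planned = 0, unplanned_wanted = -0.25,
                    unplanned_ambivalent = -0.5)
    ),
    intercept = NA_real_,  # solved below
    recognition = .solve_recognition_mixture(p_early = 0.817,
                                             mean = 5.4, sd = 2.3)
  )

  missing_rates <- vapply(names(tabled), function(v) {
    1 - sum(tabled[[v]]$total) / .calibration_n$total
  }, numeric(1))
  # recognition timing inherits the missingness of its published indicator
  missing_rates["recognition_weeks"] <-
    missing_rates[["early_recognition"]]
  missing_rates <- missing_rates[setdiff(names(missing_rates),
                                         c("early_recognition", "regular_cycle"))]
  missing_rates["regular_cycle"] <- 0
  # unpublished: parity and the three imputation auxiliaries
  missing_rates[c("parity", "bmi_intake", "ga_intake", "apgar5")] <-
    c(0.05, 0.05, 0.02, 0.08)

  params <- structure(list(
    n = as.integer(n),
    prevalences = prevalences,
    regular_cycle_prevalence = 2360 / 4196,
    exposure_model = exposure_model,
    outcome_intercept = NA_real_,  # solved below
    outcome_coefs = outcome_coefs,
    exposure_effect = -0.6,
    noise_sd = NA_real_,           # solved below
    outcome_mean = 12.9,
    outcome_sd = 3.7,
    outcome_floor = 4,
    missing_rates = missing_rates,
    # log-odds shifts that make missingness MAR: driven by low education,
    # first-generation migration and (for recognition timing) late initiation
    mar_dependence = c(education_low = 0.5, migration_first = 0.5,
                       recognition_late_initiation = 3.0),
    seed = 1L
  ), class = "cohort_params")

  calibrate_params(params)
}

#' Re-solve the calibrated intercepts of generator parameters
#'
#' Solves the exposure-model intercept so the implied marginal prevalence of
#' early recognition equals `exposure_model$target_prevalence`, then the
#' outcome intercept and residual SD so the implied marginal outcome mean and
#' SD equal `outcome_mean` and `outcome_sd`. Call after editing prevalences,
#' coefficients or targets.
#'
#' @param params A `cohort_params` object.
#' @return The parameters with `exposure_model$intercept`,
#'   `outcome_intercept` and `noise_sd` replaced by their solved values.
#' @export
calibrate_params <- function(params) {
  joint <- .exposure_joint(params)
  f <- function(a) sum(joint$w * plogis(a + joint$lp)) -
    params$exposure_model$target_prevalence
  params$exposure_model$intercept <- uniroot(f, c(-20, 20), tol = 1e-12)$root

  pbar <- params$exposure_model$target_prevalence
  mean_x <- sum(vapply(predictor_names(), function(v) {
    sum(params$prevalences[[v]] * params$outcome_coefs[[v]][names(params$prevalences[[v]])])
  }, numeric(1)))
  params$outcome_intercept <- params$outcome_mean - mean_x -
    params$exposure_effect * pbar

  # marginal outcome variance: independent predictor contributions, the
  # exposure term, and twice the exposure-confounder covariance
  var_x <- sum(vapply(predictor_names(), function(v) {
    p <- params$prevalences[[v]]
    b <- params$outcome_coefs[[v]][names(p)]
    sum(p * b^2) - sum(p * b)^2
  }, numeric(1)))
  pa <- plogis(params$exposure_model$intercept + joint$lp)
  cov_ax <- sum(vapply(names(params$exposure_model$coefs), function(v) {
    pl <- params$prevalences[[v]]
    pa_l <- tapply(joint$w * pa, joint$grid[[v]], sum) /
      tapply(joint$w, joint$grid[[v]], sum)
    b <- params$outcome_coefs[[v]][names(pl)]
    sum(pl * b * (pa_l[names(pl)] - pbar))
  }, numeric(1)))
  var_sys <- var_x + params$exposure_effect^2 * pbar * (1 - pbar) +
    2 * params$exposure_effect * cov_ax
  if (var_sys >= params$outcome_sd^2) {
    abort("systematic outcome variance exceeds the target outcome SD; reduce outcome_coefs",
          class = "ineqshift_parameter_error")
  }
  params$noise_sd <- sqrt(params$outcome_sd^2 - var_sys)
  validate_params(params)
  params
}

#' Validate generator parameters
#'
#' @param params A `cohort_params` object.
#' @return The parameters, invisibly; errors name the offending field.
#' @export
validate_params <- function(params) {
  if (!inherits(params, "cohort_params")) {
    abort("params must be a 'cohort_params' object", class = "ineqshift_parameter_error")
  }
  if (!is.numeric(params$n) || params$n < 1) {
    abort("field 'n' must be a positive integer", class = "ineqshift_parameter_error")
  }
  for (v in predictor_names()) {
    p <- params$prevalences[[v]]
    if (is.null(p) || !setequal(names(p), .predictor_levels[[v]])) {
      abort(sprintf("field 'prevalences$%s' must cover levels %s", v,
                    paste(.predictor_levels[[v]], collapse = ", ")),
            class = "ineqshift_parameter_error")
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      abort(sprintf("field 'prevalences$%s' must be a probability vector summing to 1", v),
            class = "ineqshift_parameter_error")
    }
  }
  if (!is.finite(params$noise_sd) || params$noise_sd <= 0) {
    abort("field 'noise_sd' must be positive", class = "ineqshift_parameter_error")
  }
  mr <- params$missing_rates
  if (any(mr < 0 | mr >= 1)) {
    abort("field 'missing_rates' must lie in [0, 1)", class = "ineqshift_parameter_error")
  }
  if (any(names(mr) %in% c("init_weeks", "participant_id"))) {
    abort("field 'missing_rates' may not target init_weeks (never missing by design)",
          class = "ineqshift_parameter_error")
  }
  joint <- .exposure_joint(params)
  pa <- plogis(params$exposure_model$intercept + joint$lp)
  if (any(pa <= 0 | pa >= 1)) {
    abort("field 'exposure_model' implies a stratum probability outside (0, 1)",
          class = "ineqshift_parameter_error")
  }
  invisible(params)
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("<cohort_params>\n")
  cat("  n:", x$n, "\n")
  cat("  exposure_effect:", x$exposure_effect, "weeks\n")
  cat(sprintf("  outcome: mean %.1f, sd %.1f (intercept %.3f, noise_sd %.3f)\n",
              x$outcome_mean, x$outcome_sd, x$outcome_intercept, x$noise_sd))
  cat(sprintf("  early recognition target prevalence: %.3f (logit intercept %.3f)\n",
              x$exposure_model$target_prevalence, x$exposure_model$intercept))
  cat("  variables with missingness:", sum(x$missing_rates > 0), "\n")
  invisible(x)
}

# joint distribution of the exposure-model drivers (independence copula over
# the marginal prevalences); returns cell weights and linear predictors
.exposure_joint <- function(params) {
  drivers <- names(params$exposure_model$coefs)
  grid <- expand.grid(lapply(params$prevalences[drivers], names),
                      stringsAsFactors = FALSE)
  names(grid) <- drivers
  w <- Reduce(`*`, lapply(drivers, function(v) {
    params$prevalences[[v]][grid[[v]]]
  }))
  lp <- Reduce(`+`, lapply(drivers, function(v) {
    params$exposure_model$coefs[[v]][grid[[v]]]
  }))
  list(grid = grid, w = unname(w), lp = unname(lp))
}

# moments of recognition timing given early/late recognition, solved so the
# mixture reproduces the published overall mean and SD. The early component
# is a Beta(2.7, 1.3) scaled to [2, 6] (right-heavy, mean 4.7); the late
# component is 6 weeks plus a Gamma whose two moments absorb the remainder.
.solve_recognition_mixture <- function(p_early, mean, sd) {
  shape1 <- 2.7; shape2 <- 1.3
  m_early <- 2 + 4 * shape1 / (shape1 + shape2)
  v_early <- 16 * shape1 * shape2 /
    ((shape1 + shape2)^2 * (shape1 + shape2 + 1))
  m_late <- (mean - p_early * m_early) / (1 - p_early)
  v_late <- (sd^2 - p_early * v_early - p_early * (m_early - mean)^2 -
               (1 - p_early) * (m_late - mean)^2) / (1 - p_early)
  if (m_late <= 6 || v_late <= 0) {
    abort("recognition mixture targets are infeasible at this early-recognition prevalence",
          class = "ineqshift_parameter_error")
  }
  list(early_min = 2, early_max = 6,
       early_shape1 = shape1, early_shape2 = shape2,
       late_shift = 6,
       late_shape = (m_late - 6)^2 / v_late,
       late_scale = v_late / (m_late - 6),
       late_cap = 30)
}
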