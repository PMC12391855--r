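#' Generate a complete synthetic cohort
#'
#' Draws a complete (no-missing) participant-level cohort with the statistical
#' structure the downstream analysis assumes: independent categorical
#' predictors drawn from their marginal prevalences, a binary exposure (early
#' pregnancy recognition) whose probability follows a logistic model on
#' education, income, age group and pregnancy intention, recognition timing
#' drawn consistently with the exposure (at most 6 weeks iff early), and a
#' linear outcome in weeks
#' \deqn{Y_i = \beta_0 + \sum_p \beta_p[x_{ip}] + \beta_A A_i + \varepsilon_i,
#'       \quad \varepsilon_i \sim N(0, \sigma^2),}
#' truncated below at 4 gestational weeks. Identical seeds reproduce the
#' table exactly.
#'
#' @param params A `cohort_params` object, see [default_params()].
#' @param seed Integer seed; defaults to `params$seed`.
#' @return A tibble with the columns of [cohort_columns()] and `params$n`
#'   rows, free of missing values.
#' @export
#' @examples
#' cohort <- generate_cohort(default_params(n = 500), seed = 1)
#' mean(cohort$early_recognition)
generate_cohort <- function(params, seed = params$seed) {
  validate_params(params)
  n <- params$n
  set.seed(seed)

  covs <- lapply(predictor_names(), function(v) {
    p <- params$prevalences[[v]]
    factor(sample(names(p), n, replace = TRUE, prob = p),
           levels = .predictor_levels[[v]])
  })
  names(covs) <- predictor_names()

  em <- params$exposure_model
  lp <- em$intercept
  for (v in names(em$coefs)) lp <- lp + em$coefs[[v]][as.character(covs[[v]])]
  early <- rbinom(n, 1L, plogis(lp))

  rec <- em$recognition
  recognition <- numeric(n)
  n_early <- sum(early)
  recognition[early == 1L] <- rec$early_min +
    (rec$early_max - rec$early_min) *
    rbeta(n_early, rec$early_shape1, rec$early_shape2)
  recognition[early == 0L] <- rec$late_shift +
    pmin(rgamma(n - n_early, shape = rec$late_shape, scale = rec$late_scale),
         rec$late_cap - rec$late_shift)

  xb <- params$outcome_intercept
  for (v in predictor_names()) {
    xb <- xb + params$outcome_coefs[[v]][as.character(covs[[v]])]
  }
  init <- pmax(params$outcome_floor,
               xb + params$exposure_effect * early +
                 rnorm(n, 0, params$noise_sd))

  regular <- rbinom(n, 1L, params$regular_cycle_prevalence)

  # auxiliaries: BMI loosely tied to education, intake GA shortly after the
  # first visit (hence a strong imputation predictor), Apgar mostly 9-10
  edu <- as.character(covs$education)
  bmi <- pmin(45, pmax(15, 24.5 + 0.8 * (edu == "low") + 0.4 * (edu == "medium") +
                         rnorm(n, 0, 3.8)))
  ga_intake <- init + rgamma(n, shape = 2, scale = 0.75)
  apgar5 <- pmax(0, pmin(10, 10 - rpois(n, 0.35)))

  tibble::as_tibble(c(
    list(participant_id = sprintf("P%06d", seq_len(n))),
    covs,
    list(recognition_weeks = unname(recognition),
         early_recognition = as.integer(recognition <= 6),
         init_weeks = unname(init),
         regular_cycle = regular,
         bmi_intake = bmi,
         ga_intake = ga_intake,
         apgar5 = as.numeric(apgar5))
  ))
}

#' Blank cells of a complete cohort under a MAR mechanism
#'
#' Sets cells of a complete cohort table to missing at the per-variable rates
#' in `params$missing_rates`. Missingness is missing-at-random: the log-odds
#' of a cell being blanked are shifted for participants with low education,
#' first-generation migration background, and — for recognition timing — late
#' antenatal care initiation (first visit after 14 weeks, always observed),
#' per `params$mar_dependence`. The logit intercept of each variable is
#' solved on the realised cohort so the expected marginal missingness equals
#' the requested rate exactly. Education and migration themselves are blanked
#' completely at random. `early_recognition` is blanked wherever
#' `recognition_weeks` is, preserving the derived-variable invariant;
#' `init_weeks` is never blanked (inclusion criterion).
#'
#' @param table A complete cohort table from [generate_cohort()].
#' @param params A `cohort_params` object.
#' @param seed Integer seed; defaults to `params$seed + 1`.
#' @return The cohort with missing cells, as a tibble.
#' @export
apply_missingness <- function(table, params, seed = params$seed + 1L) {
  validate_params(params)
  table <- tibble::as_tibble(table)
  n <- nrow(table)
  dep <- params$mar_dependence
  base_shift <- dep[["education_low"]] * (as.character(table$education) == "low") +
    dep[["migration_first"]] * (as.character(table$migration) == "1st_generation")

  set.seed(seed)
  for (v in names(params$missing_rates)) {
    rate <- params$missing_rates[[v]]
    if (rate <= 0) next
    if (!v %in% names(table)) next
    shift <- if (v %in% c("education", "migration")) {
      rep(0, n)  # MCAR for the MAR drivers themselves
    } else if (v == "recognition_weeks") {
      base_shift + dep[["recognition_late_initiation"]] * (table$init_weeks > 14)
    } else {
      base_shift
    }
    a <- if (all(shift == 0)) qlogis(rate) else {
      uniroot(function(a) mean(plogis(a + shift)) - rate,
              c(qlogis(rate) - 20, qlogis(rate) + 20), tol = 1e-10)$root
    }
    blank <- runif(n) < plogis(a + shift)
    table[[v]][blank] <- NA
    if (v == "recognition_weeks") table$early_recognition[blank] <- NA
  }
  table
}
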