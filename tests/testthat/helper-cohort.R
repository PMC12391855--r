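# Builders for small hand-controlled cohort tables.

# minimal complete cohort with every dictionary column, defaults constant;
# override any column by name
mini_cohort <- function(n, ...) {
  lv <- cohort_levels()
  base <- c(
    list(participant_id = sprintf("P%04d", seq_len(n))),
    lapply(lv, function(l) factor(rep(l[1], n), levels = l)),
    list(recognition_weeks = rep(5, n),
         early_recognition = rep(1L, n),
         init_weeks = rep(12, n),
         regular_cycle = rep(1L, n),
         bmi_intake = rep(24, n),
         ga_intake = rep(13, n),
         apgar5 = rep(10, n))
  )
  overrides <- list(...)
  for (v in names(overrides)) {
    x <- overrides[[v]]
    base[[v]] <- if (v %in% names(lv)) factor(as.character(x), levels = lv[[v]]) else x
  }
  base$early_recognition <- ifelse(is.na(base$recognition_weeks),
                                   base$early_recognition,
                                   as.integer(base$recognition_weeks <= 6))
  tibble::as_tibble(base)
}

# noiseless generator parameters: flat outcome, no exposure effect
degenerate_params <- function(n, intercept = 12) {
  p <- default_params(n)
  p$outcome_coefs <- lapply(p$outcome_coefs, function(b) b * 0)
  p$exposure_effect <- 0
  p$outcome_intercept <- intercept
  p$noise_sd <- 1e-9
  p
}

# parameters with the exposure drawn independently of every covariate
unconfounded_params <- function(n, prevalence = 0.817) {
  p <- default_params(n)
  p$exposure_model$coefs <- lapply(p$exposure_model$coefs, function(b) b * 0)
  p$exposure_model$target_prevalence <- prevalence
  calibrate_params(p)
}

# random small two-group table with guaranteed exposed/unexposed rows in
# every (level x exposure) cell, for oracle-equivalence checks
random_saturated_table <- function(seed) {
  set.seed(seed)
  repeat {
    n <- sample(40:200, 1)
    p_level <- runif(1, 0.25, 0.75)
    p_a <- runif(2, 0.25, 0.75)
    g <- sample(c("yes", "no"), n, replace = TRUE, prob = c(p_level, 1 - p_level))
    a <- rbinom(n, 1, ifelse(g == "yes", p_a[1], p_a[2]))
    cells <- table(g, a)
    if (all(dim(cells) == c(2, 2)) && all(cells > 0)) break
  }
  y <- 10 + 1.5 * (g == "no") - runif(1, 0, 2) * a +
    0.8 * (g == "no") * a + rnorm(n)
  tibble::tibble(
    employment = factor(g, levels = c("yes", "no")),
    early_recognition = a,
    init_weeks = y)
}
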