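# G-computation of the hypothetical intervention "everyone recognises the
# pregnancy within 6 weeks" and the inequality-reduction contrast.

#' Counterfactual outcomes under universal early recognition
#'
#' Computes each participant's outcome had everyone recognised the pregnancy
#' early (the intervention sets the exposure A to 1 for all).
#'
#' With `method = "shift"` (default) the observed outcome is shifted by the
#' adjusted exposure effect for participants without early recognition:
#' \deqn{Y^*_i = Y_i + \hat\beta_A (1 - A_i).}
#' Participants already exposed keep their observed outcome exactly
#' (consistency). For a main-effects linear model this equals model-based
#' prediction under the intervention plus the participant's residual, which
#' `method = "predict"` computes explicitly
#' (\eqn{Y^*_i = Y_i - \hat m(A_i, X_i) + \hat m(1, X_i)}) and which also
#' supports exposure-covariate interactions.
#'
#' @param table A cohort table with non-missing `early_recognition`, aligned
#'   with the estimation sample of `fit`.
#' @param fit The adjusted exposure model from
#'   [fit_adjusted_exposure_model()].
#' @param method `"shift"` or `"predict"`.
#' @return Numeric vector of counterfactual outcomes (weeks), one per row.
#' @export
#' @examples
#' cohort <- generate_cohort(default_params(n = 1000), seed = 7)
#' fit <- fit_adjusted_exposure_model(cohort)
#' ystar <- counterfactual_outcomes(cohort, fit)
#' all(ystar[cohort$early_recognition == 1] ==
#'     cohort$init_weeks[cohort$early_recognition == 1])
counterfactual_outcomes <- function(table, fit,
                                    method = c("shift", "predict")) {
  method <- match.arg(method)
  table <- .as_cohort_factors(tibble::as_tibble(table))
  if (anyNA(table$early_recognition)) {
    abort("early_recognition has missing values; counterfactuals need a completed table",
          class = "ineqshift_invariant_error")
  }
  a <- table$early_recognition
  y <- table$init_weeks
  if (method == "shift") {
    if (is.na(fit$exposure_beta)) {
      abort("fit does not carry an exposure coefficient; use fit_adjusted_exposure_model()",
            class = "ineqshift_parameter_error")
    }
    return(y + fit$exposure_beta * (1 - a))
  }
  # prediction route: keep each participant's residual
  for (p in names(fit$references)) {
    table[[p]] <- stats::relevel(table[[p]], ref = fit$references[[p]])
  }
  intervened <- table
  intervened$early_recognition <- 1L
  pred_obs <- predict(fit$model, newdata = table)
  pred_int <- predict(fit$model, newdata = intervened)
  if (length(pred_obs) != nrow(table)) {
    abort("table rows do not align with the fit's estimation sample",
          class = "ineqshift_alignment_error")
  }
  unname(y - pred_obs + pred_int)
}

#' Inequality with and without the intervention, and its reduction
#'
#' For one predictor, estimates the per-level inequality in initiation
#' timing without the intervention (regression on observed outcomes), with
#' the intervention (the same regression on counterfactual outcomes under
#' universal early recognition), and the reduction (with minus without).
#' Under the outcome-shift construction and unadjusted inequality models the
#' reduction obeys the closed form
#' \deqn{\mathrm{reduction}_l = \hat\beta_A (\bar A_{ref} - \bar A_l),}
#' i.e. an inequality shrinks exactly insofar as the level lags the
#' reference in early-recognition prevalence.
#'
#' @param table A completed cohort table.
#' @param predictor Predictor name.
#' @param fit Adjusted exposure model ([fit_adjusted_exposure_model()]).
#' @param reference Frozen reference level; defaults to [choose_reference()]
#'   on `table`.
#' @param method Counterfactual construction, see
#'   [counterfactual_outcomes()].
#' @return A tibble with one row per dictionary level: `predictor`, `level`,
#'   `is_reference`, `beta_without`, `beta_with`, `reduction`. Levels absent
#'   from the data yield `NA` estimates with a warning.
#' @export
estimate_reduction <- function(table, predictor, fit, reference = NULL,
                               method = c("shift", "predict")) {
  method <- match.arg(method)
  table <- .as_cohort_factors(tibble::as_tibble(table))
  reference <- reference %||% choose_reference(table, predictor)

  fit_without <- estimate_inequality(table, predictor, reference)
  ystar <- counterfactual_outcomes(table, fit, method = method)
  fit_with <- estimate_inequality(table, predictor, reference,
                                  outcome = ystar)
  without <- .level_contrasts(fit_without, predictor)
  with_ <- .level_contrasts(fit_with, predictor)

  out <- tibble::tibble(
    predictor = predictor,
    level = names(without),
    is_reference = names(without) == reference,
    beta_without = unname(without),
    beta_with = unname(with_),
    reduction = unname(with_ - without)
  )
  if (anyNA(out$beta_without)) {
    warn(sprintf("predictor '%s': empty level(s) %s emitted without estimates",
                 predictor,
                 paste(out$level[is.na(out$beta_without)], collapse = ", ")))
  }
  out
}

#' Brute-force standardisation oracle
#'
#' Computes the counterfactual inequality under universal early recognition
#' by exhaustive stratum-wise substitution: within each covariate stratum,
#' every unexposed participant's outcome is replaced by the stratum-specific
#' mean outcome among the exposed, then the same group-mean contrasts are
#' formed. On tables where every stratum containing unexposed rows also
#' contains exposed rows, and with an outcome model saturated in
#' (stratum x exposure), this agrees with [estimate_reduction()] exactly —
#' which is what makes it a useful independent test oracle. Intended for
#' small, coarse tables.
#'
#' @param table A cohort-like data frame with `init_weeks`,
#'   `early_recognition` and the stratification columns.
#' @param predictor Predictor whose inequality is contrasted.
#' @param covariates Columns defining the standardisation strata; defaults
#'   to the predictor itself.
#' @return A tibble shaped like [estimate_reduction()]'s output.
#' @export
standardization_oracle <- function(table, predictor,
                                   covariates = predictor) {
  table <- tibble::as_tibble(table)
  a <- table$early_recognition
  y <- table$init_weeks
  strata <- interaction(table[covariates], drop = TRUE)

  ystar <- y
  for (s in levels(strata)) {
    rows <- strata == s
    unexposed <- rows & a == 0
    if (!any(unexposed)) next
    exposed <- rows & a == 1
    if (!any(exposed)) {
      abort(sprintf("positivity violation: stratum '%s' has unexposed rows but no exposed counterpart", s),
            class = "ineqshift_positivity_error")
    }
    ystar[unexposed] <- mean(y[exposed])
  }

  f <- factor(as.character(table[[predictor]]),
              levels = if (predictor %in% names(.predictor_levels)) {
                .predictor_levels[[predictor]]
              } else sort(unique(as.character(table[[predictor]]))))
  f <- droplevels(f)
  means_without <- as.numeric(tapply(y, f, mean))
  means_with <- as.numeric(tapply(ystar, f, mean))
  r <- which.min(means_without)

  tibble::tibble(
    predictor = predictor,
    level = levels(f),
    is_reference = seq_along(means_without) == r,
    beta_without = means_without - means_without[r],
    beta_with = means_with - means_with[r],
    reduction = (means_with - means_with[r]) -
      (means_without - means_without[r])
  )
}
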