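# Per-predictor inequality regressions and the adjusted exposure model.

#' Choose the reference level of a predictor
#'
#' The reference is the level with the earliest mean antenatal care
#' initiation (smallest mean `init_weeks`), so every inequality contrast is
#' non-negative in expectation. Ties are broken by dictionary order, empty
#' levels are excluded with a warning, and the choice is made once on the
#' observed data and reused for counterfactual scenarios.
#'
#' @param table A cohort table.
#' @param predictor Name of one of [predictor_names()].
#' @return The reference level as a character scalar.
#' @export
#' @examples
#' cohort <- generate_cohort(default_params(n = 2000), seed = 3)
#' choose_reference(cohort, "education")
choose_reference <- function(table, predictor) {
  table <- .as_cohort_factors(tibble::as_tibble(table))
  f <- table[[predictor]]
  if (is.null(f)) abort(sprintf("unknown predictor '%s'", predictor),
                        class = "ineqshift_parameter_error")
  keep <- !is.na(f)
  means <- tapply(table$init_weeks[keep], f[keep], mean)  # dictionary order
  empty <- names(means)[is.na(means)]
  if (length(empty) > 0) {
    warn(sprintf("predictor '%s': level(s) %s have no rows and are excluded from reference candidacy",
                 predictor, paste(empty, collapse = ", ")))
  }
  if (sum(!is.na(means)) < 2) {
    abort(sprintf("predictor '%s' needs at least 2 non-empty levels", predictor),
          class = "ineqshift_parameter_error")
  }
  names(means)[which.min(means)]  # which.min: first minimum in level order
}

#' Estimate the inequality in initiation timing for one predictor
#'
#' Ordinary least squares of gestational age at the first antenatal visit on
#' indicator variables for the non-reference levels of a single predictor:
#' each coefficient is the mean difference in weeks versus the reference
#' level (the unadjusted, one-predictor-at-a-time association). The fit uses
#' R's rank-revealing QR, so a level emptied by subsetting is dropped and
#' recorded rather than crashing the fit.
#'
#' @param table A cohort table (rows with a missing predictor value are
#'   dropped).
#' @param predictor Name of the predictor.
#' @param reference Reference level; defaults to [choose_reference()].
#' @param outcome Optional replacement outcome vector aligned with `table`
#'   (used for counterfactual scenarios); defaults to `table$init_weeks`.
#' @param adjusted If `TRUE`, fits the mutually adjusted variant with main
#'   effects of all other predictors alongside this one.
#' @return An `ineq_fit` object: coefficients, covariance, residual variance,
#'   rows used, the reference, and any dropped terms.
#' @export
estimate_inequality <- function(table, predictor, reference = NULL,
                                outcome = NULL, adjusted = FALSE) {
  table <- .as_cohort_factors(tibble::as_tibble(table))
  reference <- reference %||% choose_reference(table, predictor)
  if (!reference %in% levels(table[[predictor]])) {
    abort(sprintf("'%s' is not a level of predictor '%s'", reference, predictor),
          class = "ineqshift_parameter_error")
  }
  dat <- table
  dat$.y <- outcome %||% dat$init_weeks
  dat[[predictor]] <- stats::relevel(dat[[predictor]], ref = reference)
  rhs <- if (adjusted) paste(predictor_names(), collapse = " + ") else predictor
  fit <- lm(as.formula(paste(".y ~", rhs)), data = dat, na.action = na.omit)
  .new_ineq_fit(fit, predictor = predictor, reference = reference,
                references = setNames(reference, predictor))
}

#' Fit the adjusted exposure model
#'
#' OLS of initiation timing on early pregnancy recognition plus main-effect
#' indicators for all predictors; the coefficient on `early_recognition` is
#' the adjusted exposure effect in weeks (how much earlier care starts under
#' early recognition, all measured confounders held fixed). This model
#' supplies the effect used by the hypothetical-intervention shift.
#'
#' @param table A cohort table with non-missing `early_recognition` (i.e.
#'   post-imputation, or a complete synthetic cohort).
#' @param predictors Adjustment set; defaults to all of [predictor_names()]
#'   present in the table.
#' @param references Named character vector of reference levels per
#'   predictor; defaults to [choose_reference()] applied to `table`.
#' @param interactions If `TRUE`, fully interacts the exposure with the
#'   adjustment set (a saturated model when the adjustment set is one
#'   factor), enabling the prediction-based counterfactual.
#' @return An `ineq_fit`; the exposure coefficient is in
#'   `fit$exposure_beta`.
#' @export
#' @examples
#' cohort <- generate_cohort(default_params(n = 3000), seed = 5)
#' fit <- fit_adjusted_exposure_model(cohort)
#' fit$exposure_beta
fit_adjusted_exposure_model <- function(table, predictors = NULL,
                                        references = NULL,
                                        interactions = FALSE) {
  table <- .as_cohort_factors(tibble::as_tibble(table))
  predictors <- predictors %||% intersect(predictor_names(), names(table))
  if (anyNA(table$early_recognition)) {
    abort("early_recognition has missing values; impute before fitting the exposure model",
          class = "ineqshift_invariant_error")
  }
  if (is.null(references)) {
    references <- vapply(predictors, function(p) choose_reference(table, p),
                         character(1))
  }
  for (p in predictors) {
    table[[p]] <- stats::relevel(table[[p]], ref = references[[p]])
  }
  rhs <- paste(predictors, collapse = " + ")
  fml <- if (interactions) {
    paste("init_weeks ~ early_recognition * (", rhs, ")")
  } else {
    paste("init_weeks ~ early_recognition +", rhs)
  }
  fit <- lm(as.formula(fml), data = table, na.action = na.omit)
  .new_ineq_fit(fit, predictor = NULL, reference = NULL,
                references = references, exposure = TRUE)
}

.new_ineq_fit <- function(fit, predictor, reference, references,
                          exposure = FALSE) {
  cf <- coef(fit)
  dropped <- names(cf)[is.na(cf)]
  if (length(dropped) > 0) {
    warn(paste0("collinear/empty design columns dropped: ",
                paste(dropped, collapse = ", ")))
  }
  cf_ok <- cf[!is.na(cf)]
  out <- structure(list(
    model = fit,
    terms = names(cf_ok),
    coefs = cf_ok,
    vcov = suppressWarnings(vcov(fit)),  # silence the perfect-fit caveat
    n = length(fit$residuals),
    sigma2 = sum(fit$residuals^2) / fit$df.residual,
    predictor = predictor,
    reference = reference,
    references = references,
    dropped = dropped,
    exposure_beta = if (exposure) unname(cf_ok["early_recognition"]) else NA_real_
  ), class = "ineq_fit")
  out
}

#' @export
print.ineq_fit <- function(x, ...) {
  if (!is.na(x$exposure_beta)) {
    cat(sprintf("<ineq_fit: adjusted exposure model, n = %d>\n", x$n))
    cat(sprintf("  early recognition effect: %.3f weeks\n", x$exposure_beta))
  } else {
    cat(sprintf("<ineq_fit: inequality model for '%s' (reference '%s'), n = %d>\n",
                x$predictor, x$reference, x$n))
  }
  invisible(x)
}

#' Tidy an inequality or exposure model fit
#'
#' @param x An `ineq_fit`.
#' @param conf_level Confidence level for the normal-theory interval.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std_error`, `conf_low`,
#'   `conf_high`.
#' @export
tidy.ineq_fit <- function(x, conf_level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))[x$terms]
  z <- qt(1 - (1 - conf_level) / 2, df = x$model$df.residual)
  tibble::tibble(term = x$terms, estimate = unname(x$coefs),
                 std_error = unname(se),
                 conf_low = unname(x$coefs - z * se),
                 conf_high = unname(x$coefs + z * se))
}

#' @rdname tidy.ineq_fit
#' @export
glance.ineq_fit <- function(x, ...) {
  tibble::tibble(n = x$n, sigma2 = x$sigma2,
                 exposure_beta = x$exposure_beta,
                 n_terms = length(x$terms),
                 n_dropped = length(x$dropped))
}

# per-level contrasts (weeks vs reference) from an unadjusted single-predictor
# fit, expanded over the full level dictionary; empty levels come back NA
.level_contrasts <- function(fit, predictor) {
  lv <- .predictor_levels[[predictor]]
  out <- setNames(rep(NA_real_, length(lv)), lv)
  out[fit$reference] <- 0
  for (l in setdiff(lv, fit$reference)) {
    term <- paste0(predictor, l)
    if (term %in% fit$terms) out[l] <- unname(fit$coefs[term])
  }
  out
}
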