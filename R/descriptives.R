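# Descriptive table, dichotomisations, positivity diagnostics and the
# regular-cycle sensitivity subset.

#' Dichotomise recognition timing at 6 weeks
#'
#' Early pregnancy recognition means knowing of the pregnancy within 6 weeks
#' of the first day of the last menstrual period; the boundary is inclusive.
#' Missing values propagate.
#'
#' @param recognition_weeks Gestational weeks at recognition (non-negative
#'   or `NA`).
#' @param threshold Boundary in weeks (default 6).
#' @return Integer vector of 0/1/NA.
#' @export
#' @examples
#' dichotomize_early(c(5, 6, 6.1, NA))
dichotomize_early <- function(recognition_weeks, threshold = 6) {
  if (any(recognition_weeks < 0, na.rm = TRUE)) {
    abort("recognition_weeks must be non-negative", class = "ineqshift_domain_error")
  }
  as.integer(recognition_weeks <= threshold)
}

#' Dichotomise initiation timing at 14 weeks
#'
#' Timely initiation means a first antenatal visit at 14 gestational weeks
#' or earlier (inclusive boundary, the national basic-care recommendation at
#' the time of data collection). The outcome is never missing, so missing
#' input is an error.
#'
#' @param init_weeks Gestational weeks at the first visit (positive).
#' @param threshold Boundary in weeks (default 14).
#' @return Integer vector of 0/1.
#' @export
#' @examples
#' dichotomize_timely(c(12.9, 14, 15))
dichotomize_timely <- function(init_weeks, threshold = 14) {
  if (anyNA(init_weeks)) {
    abort("init_weeks may not be missing", class = "ineqshift_domain_error")
  }
  if (any(init_weeks <= 0)) {
    abort("init_weeks must be positive", class = "ineqshift_domain_error")
  }
  as.integer(init_weeks <= threshold)
}

#' Descriptive characteristics table
#'
#' For every categorical study variable (the 13 predictors, early
#' recognition, cycle regularity), counts and column percentages over the
#' total sample and within the timely (first visit at most 14 weeks) and
#' late strata. Percentages use the variable's non-missing rows within each
#' stratum as denominator and are rounded to 1 decimal.
#'
#' @param table A (non-imputed) cohort table.
#' @return A tibble: `variable`, `level`, `n_total`, `pct_total`,
#'   `n_timely`, `pct_timely`, `n_late`, `pct_late`.
#' @export
make_table1 <- function(table) {
  table <- .as_cohort_factors(tibble::as_tibble(table))
  timely <- dichotomize_timely(table$init_weeks) == 1L

  vars <- c(as.list(table[predictor_names()]),
            list(early_recognition = factor(
                   c("no", "yes")[table$early_recognition + 1L],
                   levels = c("no", "yes")),
                 regular_cycle = factor(
                   c("irregular_or_unknown", "regular")[table$regular_cycle + 1L],
                   levels = c("irregular_or_unknown", "regular"))))

  purrr::imap_dfr(vars, function(f, v) {
    count_stratum <- function(keep) {
      x <- f[keep]
      n <- tapply(rep(1L, sum(!is.na(x))), x[!is.na(x)], sum)
      n[is.na(n)] <- 0L
      n
    }
    nt <- count_stratum(rep(TRUE, length(f)))
    ny <- count_stratum(timely)
    nl <- count_stratum(!timely)
    tibble::tibble(
      variable = v, level = names(nt),
      n_total = as.integer(nt),
      pct_total = as.numeric(round(100 * nt / sum(nt), 1)),
      n_timely = as.integer(ny),
      pct_timely = as.numeric(round(100 * ny / sum(ny), 1)),
      n_late = as.integer(nl),
      pct_late = as.numeric(round(100 * nl / sum(nl), 1)))
  })
}

#' Positivity diagnostic via propensity scores
#'
#' Fits a logistic regression of early pregnancy recognition on all
#' predictors over the complete-case rows of the non-imputed data, and
#' reports the fitted probabilities. Positivity requires every covariate
#' pattern to retain a non-zero probability of the intervention; the report
#' therefore centres on the minimum fitted score, and a warning is emitted
#' when it falls below `floor`.
#'
#' @param table A cohort table.
#' @param floor Warning threshold for the minimum fitted probability.
#' @return An object of class `propensity_report`: `probabilities`,
#'   `minimum`, `maximum`, `model_terms`, `n`.
#' @export
check_positivity <- function(table, floor = 0.01) {
  table <- .as_cohort_factors(tibble::as_tibble(table))
  preds <- intersect(predictor_names(), names(table))
  cc <- complete.cases(table[c(preds, "early_recognition")])
  dat <- table[cc, , drop = FALSE]
  if (nrow(dat) == 0) {
    abort("no complete-case rows for the positivity model",
          class = "ineqshift_parameter_error")
  }
  # perfect separation: a populated level whose rows are all exposed or all
  # unexposed makes the MLE diverge; name the offending covariate
  for (p in preds) {
    tab <- table(dat[[p]], dat$early_recognition)
    lvl_n <- rowSums(tab)
    sep <- lvl_n > 0 & (tab[, "0"] == 0 | tab[, "1"] == 0)
    if (ncol(tab) < 2 || any(sep)) {
      bad <- if (ncol(tab) < 2) rownames(tab)[lvl_n > 0] else rownames(tab)[sep]
      abort(sprintf("perfect separation: level(s) %s of '%s' have constant exposure",
                    paste(bad, collapse = ", "), p),
            class = "ineqshift_separation_error")
    }
  }
  fml <- as.formula(paste("early_recognition ~", paste(preds, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, data = dat, family = stats::binomial()))
  probs <- stats::fitted(fit)
  report <- structure(list(probabilities = unname(probs),
                           minimum = min(probs), maximum = max(probs),
                           model_terms = names(coef(fit)), n = nrow(dat)),
                      class = "propensity_report")
  if (report$minimum < floor) {
    warn(sprintf("minimum propensity score %.4f falls below the %.2f floor",
                 report$minimum, floor))
  }
  report
}

#' @export
print.propensity_report <- function(x, ...) {
  cat(sprintf("<propensity_report: n = %d, fitted scores in [%.3f, %.3f]>\n",
              x$n, x$minimum, x$maximum))
  invisible(x)
}

#' @rdname check_positivity
#' @param x A `propensity_report`.
#' @param ... Unused.
#' @export
glance.propensity_report <- function(x, ...) {
  tibble::tibble(n = x$n, minimum = x$minimum, maximum = x$maximum,
                 n_terms = length(x$model_terms))
}

#' Restrict to participants with a regular menstrual cycle
#'
#' The consistency assumption of the hypothetical intervention (take a test
#' when a period is late) is most plausible for participants with a regular
#' cycle (28 +/- 4 days); the sensitivity analysis reruns the whole pipeline
#' on this subset.
#'
#' @param table A cohort table with a `regular_cycle` column.
#' @return The subset with `regular_cycle == 1`, as a tibble.
#' @export
filter_regular_cycle <- function(table) {
  table <- tibble::as_tibble(table)
  if (!"regular_cycle" %in% names(table)) {
    abort("column 'regular_cycle' is required", class = "ineqshift_column_error")
  }
  out <- dplyr::filter(table, .data$regular_cycle == 1)
  if (nrow(out) == 0) {
    abort("no participants with a regular cycle", class = "ineqshift_parameter_error")
  }
  out
}
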