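# Column dictionary for the participant-level cohort table.
#
# The 13 categorical predictors, the binary exposure (early pregnancy
# recognition), the continuous outcome (gestational age in weeks at the first
# antenatal care visit), the cycle-regularity flag used by the sensitivity
# analysis, and three continuous imputation auxiliaries.

.predictor_levels <- list(
  age_group      = c("<20", "20-25", "25-30", "30-35", ">=35"),
  migration      = c("none", "2nd_generation", "1st_generation"),
  relationship   = c("partner", "single"),
  intention      = c("planned", "unplanned_wanted", "unplanned_ambivalent"),
  mental_illness = c("no", "ever", "recent"),
  language       = c("sufficient", "reasonable", "insufficient"),
  parity         = c("0", "1", "2", ">=3"),
  education      = c("high", "medium", "low"),
  employment     = c("yes", "no"),
  income         = c("high", "medium", "low"),
  housing        = c("own", "rented"),
  deprivation    = c("low", "medium", "high"),
  iq             = c(">=85", "70-85", "<70")
)

.binary_cols     <- c("early_recognition", "regular_cycle")
.continuous_cols <- c("recognition_weeks", "init_weeks",
                      "bmi_intake", "ga_intake", "apgar5")

#' Cohort column dictionary
#'
#' The declared level sets of the 13 categorical predictors of antenatal care
#' initiation timing (individual factors: age group, migration background,
#' relationship status, pregnancy intention, mental illness, Dutch language
#' skills, parity; socioeconomic factors: education, employment, household
#' income, housing, neighbourhood deprivation; plus cognitive functioning).
#' The first level of each predictor is its dictionary-order head, used only
#' for tie-breaking; analysis reference levels are chosen empirically by
#' [choose_reference()].
#'
#' @return Named list of character vectors, one per predictor.
#' @seealso [cohort_columns()] for the full column set.
#' @export
#' @examples
#' cohort_levels()$education
cohort_levels <- function() .predictor_levels

#' Names of the cohort predictors
#'
#' @return Character vector of the 13 predictor column names, in dictionary
#'   order.
#' @export
predictor_names <- function() names(.predictor_levels)

#' Full cohort column set
#'
#' @return Character vector of every column a cohort table carries:
#'   participant id, the 13 predictors, recognition timing and its binary
#'   early-recognition indicator, the outcome, cycle regularity, and the three
#'   imputation auxiliaries.
#' @export
cohort_columns <- function() {
  c("participant_id", names(.predictor_levels),
    "recognition_weeks", "early_recognition", "init_weeks",
    "regular_cycle", "bmi_intake", "ga_intake", "apgar5")
}

#' Validate a cohort table
#'
#' Checks the structural invariants of a participant-level cohort table: all
#' required columns present, every categorical value inside its declared level
#' dictionary, the outcome (`init_weeks`) strictly positive and never missing,
#' `recognition_weeks` non-negative, and `early_recognition` equal to
#' `recognition_weeks <= 6` wherever recognition timing is observed.
#'
#' @param table A data frame with the columns of [cohort_columns()].
#' @return The table, invisibly, as a tibble with predictor columns coerced to
#'   factors on their dictionary levels.
#' @export
validate_cohort <- function(table) {
  table <- tibble::as_tibble(table)
  missing_cols <- setdiff(cohort_columns(), names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort table lacks required columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "ineqshift_column_error")
  }
  for (v in predictor_names()) {
    vals <- as.character(table[[v]])
    bad <- !is.na(vals) & !(vals %in% .predictor_levels[[v]])
    if (any(bad)) {
      abort(sprintf("column '%s' has undeclared level(s) %s at row(s) %s",
                    v, paste(unique(vals[bad]), collapse = ", "),
                    paste(head(which(bad), 5), collapse = ", ")),
            class = "ineqshift_level_error")
    }
    table[[v]] <- factor(vals, levels = .predictor_levels[[v]])
  }
  if (anyNA(table$init_weeks)) {
    abort("init_weeks must be observed for every participant (inclusion criterion)",
          class = "ineqshift_invariant_error")
  }
  if (any(table$init_weeks <= 0)) {
    abort("init_weeks must be positive gestational weeks",
          class = "ineqshift_invariant_error")
  }
  if (any(table$recognition_weeks < 0, na.rm = TRUE)) {
    abort("recognition_weeks must be non-negative",
          class = "ineqshift_invariant_error")
  }
  obs <- !is.na(table$recognition_weeks) & !is.na(table$early_recognition)
  implied <- as.integer(table$recognition_weeks[obs] <= 6)
  if (any(table$early_recognition[obs] != implied)) {
    abort("early_recognition disagrees with recognition_weeks <= 6",
          class = "ineqshift_invariant_error")
  }
  invisible(table)
}

# internal: coerce predictor columns to dictionary factors without full checks
.as_cohort_factors <- function(table) {
  for (v in intersect(predictor_names(), names(table))) {
    if (!is.factor(table[[v]]) ||
        !identical(levels(table[[v]]), .predictor_levels[[v]])) {
      table[[v]] <- factor(as.character(table[[v]]),
                           levels = .predictor_levels[[v]])
    }
  }
  table
}
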