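# CSV readers/writers for the cohort table. Categorical levels are
# serialised as the literal dictionary strings; missing cells are empty.

#' Read a cohort table from CSV
#'
#' Reads a participant-level CSV against the documented column dictionary:
#' snake_case headers per [cohort_columns()], categorical levels as the
#' literal strings of [cohort_levels()] (case-sensitive), empty cells as
#' missing. Extra columns are dropped with a warning; absent required
#' columns or undeclared category labels are errors (with row numbers).
#' If `early_recognition` is absent or blank where `recognition_weeks` is
#' observed, it is derived as `recognition_weeks <= 6`.
#'
#' @param path CSV file path.
#' @return A validated cohort tibble.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file '%s' does not exist", path), class = "ineqshift_io_error")
  }
  raw <- readr::read_csv(path, na = "", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  extra <- setdiff(names(raw), cohort_columns())
  if (length(extra) > 0) {
    warn(paste0("ignoring unknown column(s): ", paste(extra, collapse = ", ")))
    raw <- raw[setdiff(names(raw), extra)]
  }
  required <- setdiff(cohort_columns(), "early_recognition")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
          class = "ineqshift_column_error")
  }
  for (v in c(.continuous_cols, "bmi_intake", "ga_intake", "apgar5")) {
    raw[[v]] <- as.numeric(raw[[v]])
  }
  for (v in .binary_cols) {
    if (v %in% names(raw)) raw[[v]] <- as.integer(raw[[v]])
  }
  if (!"early_recognition" %in% names(raw)) {
    raw$early_recognition <- NA_integer_
  }
  derive <- is.na(raw$early_recognition) & !is.na(raw$recognition_weeks)
  raw$early_recognition[derive] <- as.integer(raw$recognition_weeks[derive] <= 6)
  validate_cohort(raw)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort_csv()]: write-then-read reproduces the table,
#' including its missingness pattern.
#'
#' @param table A cohort table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  table <- tibble::as_tibble(table)[intersect(cohort_columns(), names(table))]
  out <- dplyr::mutate(table, dplyr::across(dplyr::where(is.factor), as.character))
  readr::write_csv(out, path, na = "")
  invisible(path)
}
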