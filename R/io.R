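# Cohort CSV reading and writing.
#
# CSV is the sole cohort format: header with exactly the cohort column
# names, booleans as 0/1, missing event_code as the empty string. Numbers
# are written with full precision so a write/read round-trip is lossless.

#' Read a cohort CSV
#'
#' Validates the header, column types, and record invariants; failures
#' report the offending field and row numbers.
#'
#' @param path Path to a cohort CSV (see [write_cohort()] for the format).
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such cohort file: %s", path))
  cohort <- readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      sex = readr::col_character(),
      age = readr::col_double(),
      total_cholesterol = readr::col_double(),
      hdl = readr::col_double(),
      ldl = readr::col_double(),
      triglycerides = readr::col_double(),
      fasting_glucose = readr::col_double(),
      bmi = readr::col_double(),
      sbp = readr::col_double(),
      bp_treated = readr::col_integer(),
      smoker = readr::col_integer(),
      diabetes = readr::col_integer(),
      prior_cvd = readr::col_integer(),
      event = readr::col_integer(),
      event_code = readr::col_character(),
      followup_years = readr::col_double()
    ),
    na = character(),
    show_col_types = FALSE
  )
  problems <- readr::problems(cohort)
  if (nrow(problems) > 0) {
    abort(sprintf(
      "cohort CSV parse failure at row %d, column %s",
      problems$row[1], problems$col[1]
    ))
  }
  validate_cohort(cohort)
  cohort
}

#' Write a cohort CSV
#'
#' @param cohort A validated cohort.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  out <- cohort[, cohort_columns()]
  for (col in .flag_cols) out[[col]] <- as.integer(out[[col]])
  readr::write_csv(out, path)
  invisible(path)
}
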