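# Cohort data model: schema, validation, filters, ICD-10 outcome mapping.

#' Cohort column schema
#'
#' One row per participant. Continuous covariates are strictly positive;
#' `event` marks a composite cardiovascular event within the 10-year
#' follow-up window, in which case `event_code` carries the ICD-10 code and
#' `followup_years` the time to the event; participants without an event
#' are administratively censored at exactly 10 years.
#'
#' @return A character vector of required column names.
#' @export
cohort_columns <- function() {
  c(
    "id", "sex", "age", "total_cholesterol", "hdl", "ldl", "triglycerides",
    "fasting_glucose", "bmi", "sbp", "bp_treated", "smoker", "diabetes",
    "prior_cvd", "event", "event_code", "followup_years"
  )
}

.continuous_cols <- c(
  "age", "total_cholesterol", "hdl", "ldl", "triglycerides",
  "fasting_glucose", "bmi", "sbp"
)
.flag_cols <- c("bp_treated", "smoker", "diabetes", "prior_cvd", "event")

#' Validate a cohort data frame
#'
#' Checks the column set, types, and the per-record invariants: strictly
#' positive continuous covariates, `event` consistent with `event_code`
#' (present if and only if an event occurred, and a member of the composite
#' code set), `followup_years` in (0, 10] with censoring at exactly 10 for
#' non-events. Failure messages name the offending field and row numbers.
#'
#' @param cohort A data frame with the columns of [cohort_columns()].
#' @return The cohort as a tibble, invisibly unchanged, if valid.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) abort("`cohort` must be a data frame.")
  cohort <- tibble::as_tibble(cohort)
  missing <- setdiff(cohort_columns(), names(cohort))
  if (length(missing) > 0) {
    abort(paste0("cohort is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(cohort) == 0) return(invisible(cohort))

  fail <- function(field, rows, what) {
    abort(sprintf(
      "invalid cohort: field `%s` %s at row(s) %s", field, what,
      paste(head(rows, 5), collapse = ", ")
    ))
  }
  if (!all(cohort$sex %in% c("male", "female"))) {
    fail("sex", which(!cohort$sex %in% c("male", "female")), "must be 'male' or 'female'")
  }
  for (col in .continuous_cols) {
    x <- cohort[[col]]
    if (!is.numeric(x)) fail(col, seq_len(nrow(cohort)), "must be numeric")
    bad <- which(!is.finite(x) | x <= 0)
    if (length(bad) > 0) fail(col, bad, "must be finite and strictly positive")
  }
  for (col in .flag_cols) {
    x <- cohort[[col]]
    ok <- is.logical(x) || (is.numeric(x) && all(x %in% c(0, 1)))
    if (!ok) fail(col, seq_len(nrow(cohort)), "must be logical or 0/1")
  }
  ev <- as.logical(cohort$event)
  code <- cohort$event_code
  has_code <- !is.na(code) & nzchar(code)
  bad <- which(ev != has_code)
  if (length(bad) > 0) fail("event_code", bad, "must be present exactly when event is true")
  bad <- which(has_code & !map_outcome(ifelse(has_code, code, "I63"))$composite_cvd)
  if (length(bad) > 0) fail("event_code", bad, "is not in the composite CVD code set")
  fy <- cohort$followup_years
  bad <- which(!is.finite(fy) | fy <= 0 | fy > 10)
  if (length(bad) > 0) fail("followup_years", bad, "must lie in (0, 10]")
  bad <- which(!ev & fy != 10)
  if (length(bad) > 0) fail("followup_years", bad, "must equal 10 for non-events (administrative censoring)")
  invisible(cohort)
}

#' Exclusion rules for cohort assembly
#'
#' Defaults follow the study design this package emulates: drop
#' participants under 30 years of age, those with prior cardiovascular
#' disease, and biologically implausible outliers (total cholesterol
#' > 300 mg/dL, HDL > 100 mg/dL, BMI > 100 kg/m^2, LDL > 1000 mg/dL,
#' triglycerides > 1500 mg/dL).
#'
#' @param min_age Minimum age in years (exclusive lower bound is `age < min_age`).
#' @param exclude_prior_cvd Drop records with `prior_cvd = TRUE`?
#' @param total_cholesterol_max,hdl_max,bmi_max,ldl_max,triglycerides_max
#'   Outlier thresholds (strictly greater than the threshold excludes).
#' @return An object of class `exclusion_rules`.
#' @export
exclusion_rules <- function(min_age = 30, exclude_prior_cvd = TRUE,
                            total_cholesterol_max = 300, hdl_max = 100,
                            bmi_max = 100, ldl_max = 1000,
                            triglycerides_max = 1500) {
  thresholds <- c(
    total_cholesterol_max = total_cholesterol_max, hdl_max = hdl_max,
    bmi_max = bmi_max, ldl_max = ldl_max, triglycerides_max = triglycerides_max
  )
  if (any(thresholds <= 0)) abort("outlier thresholds must be strictly positive")
  if (min_age < 0) abort("`min_age` must be non-negative")
  structure(
    list(
      min_age = min_age, exclude_prior_cvd = exclude_prior_cvd,
      total_cholesterol_max = total_cholesterol_max, hdl_max = hdl_max,
      bmi_max = bmi_max, ldl_max = ldl_max,
      triglycerides_max = triglycerides_max
    ),
    class = "exclusion_rules"
  )
}

#' Apply eligibility and outlier exclusions to a cohort
#'
#' Records violating several rules are attributed to the first rule they
#' violate, in a fixed order (under-age, prior CVD, then each outlier
#' threshold), so exclusion counts are deterministic and sum to the number
#' of excluded records.
#'
#' @param cohort A validated cohort data frame.
#' @param rules An [exclusion_rules()] object.
#' @return The retained cohort as a tibble, with the per-rule count table
#'   attached as attribute `"exclusion_log"` (retrieve it with
#'   [exclusion_log()]).
#' @export
apply_exclusions <- function(cohort, rules = exclusion_rules()) {
  stopifnot(inherits(rules, "exclusion_rules"))
  cohort <- validate_cohort(cohort)
  n <- nrow(cohort)
  rule_names <- c(
    "under_age", "prior_cvd", "tc_outlier", "hdl_outlier",
    "bmi_outlier", "ldl_outlier", "tg_outlier"
  )
  if (n == 0) {
    log <- tibble::tibble(rule = rule_names, n_excluded = 0L)
    return(structure(cohort, exclusion_log = log))
  }
  viol <- cbind(
    under_age = cohort$age < rules$min_age,
    prior_cvd = rules$exclude_prior_cvd & as.logical(cohort$prior_cvd),
    tc_outlier = cohort$total_cholesterol > rules$total_cholesterol_max,
    hdl_outlier = cohort$hdl > rules$hdl_max,
    bmi_outlier = cohort$bmi > rules$bmi_max,
    ldl_outlier = cohort$ldl > rules$ldl_max,
    tg_outlier = cohort$triglycerides > rules$triglycerides_max
  )
  first_rule <- apply(viol, 1L, function(v) if (any(v)) which(v)[1L] else 0L)
  counts <- vapply(seq_along(rule_names), function(k) sum(first_rule == k), integer(1))
  log <- tibble::tibble(rule = rule_names, n_excluded = counts)
  kept <- cohort[first_rule == 0L, , drop = FALSE]
  stopifnot(nrow(kept) + sum(counts) == n)
  structure(kept, exclusion_log = log)
}

#' Retrieve the exclusion log attached by [apply_exclusions()]
#'
#' @param cohort A cohort returned by [apply_exclusions()].
#' @return A tibble with columns `rule` and `n_excluded`.
#' @export
exclusion_log <- function(cohort) {
  log <- attr(cohort, "exclusion_log")
  if (is.null(log)) abort("no exclusion log attached; run apply_exclusions() first")
  log
}

#' Restrict a cohort to a risk engine's age window
#'
#' The Framingham general-CVD equation was developed for ages 30-74 and the
#' pooled cohort ASCVD equations for ages 40-79; records outside the window
#' are dropped before scoring.
#'
#' @param cohort A validated cohort.
#' @param engine `"framingham"` or `"ascvd"`.
#' @param age_range Optional length-2 numeric overriding the default window.
#' @return The age-eligible subset as a tibble.
#' @export
engine_eligibility <- function(cohort, engine = c("framingham", "ascvd"),
                               age_range = NULL) {
  engine <- match.arg(engine)
  cohort <- validate_cohort(cohort)
  if (is.null(age_range)) {
    age_range <- switch(engine, framingham = c(30, 74), ascvd = c(40, 79))
  }
  stopifnot(length(age_range) == 2, age_range[1] <= age_range[2])
  dplyr::filter(cohort, .data$age >= age_range[1], .data$age <= age_range[2])
}

.composite_subtypes <- c(
  I20 = "Angina pectoris",
  I21 = "Acute myocardial infarction",
  I46 = "Cardiac arrest",
  I48 = "Atrial fibrillation and flutter",
  I50 = "Heart failure",
  I60 = "Subarachnoid hemorrhage",
  I61 = "Intracerebral hemorrhage",
  I62 = "Other nontraumatic intracranial hemorrhage",
  I63 = "Cerebral infarction",
  I64 = "Stroke, not specified as haemorrhage or infarction",
  G45 = "Transient cerebral ischemic attacks and related syndromes"
)

#' Composite cardiovascular outcome codes
#'
#' The composite outcome covers ischaemic heart disease (I20-I21), atrial
#' fibrillation/flutter and heart failure (I48, I50), cardiac arrest (I46),
#' haemorrhagic stroke (I60-I62), and ischaemic stroke (I63-I64, G45).
#'
#' @return Named character vector: names are 3-character ICD-10 categories,
#'   values the subtype descriptions.
#' @export
composite_cvd_codes <- function() .composite_subtypes

#' Map ICD-10 codes to the composite cardiovascular outcome
#'
#' Matching is on the 3-character ICD-10 category, so subcodes such as
#' `"I21.4"` or `"I634"` map through their category. Unknown codes map to
#' not-CVD rather than erroring, as befits claims data.
#'
#' @param icd_code Character vector of ICD-10 codes.
#' @return A tibble with columns `icd_code`, `category` (the 3-character
#'   prefix), `composite_cvd` (logical) and `subtype` (description, `NA`
#'   for non-composite codes).
#' @export
map_outcome <- function(icd_code) {
  if (!is.character(icd_code) || any(is.na(icd_code)) || any(!nzchar(icd_code))) {
    abort("`icd_code` must be non-empty strings")
  }
  category <- toupper(substr(icd_code, 1, 3))
  hit <- category %in% names(.composite_subtypes)
  tibble::tibble(
    icd_code = icd_code,
    category = category,
    composite_cvd = hit,
    subtype = ifelse(hit, unname(.composite_subtypes[category]), NA_character_)
  )
}
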