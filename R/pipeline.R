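# End-to-end pipeline: simulate (or read) a cohort per sex, apply the
# filter cascade, score both engines, evaluate discrimination and
# calibration, run the cross-sex coefficient transfer, the data-driven
# subset search, and the variance-importance tables.

#' Pipeline run configuration
#'
#' @param n_male,n_female Synthetic cohort sizes (ignored when `cohort_paths`
#'   is given).
#' @param cohort_paths Optional named list (`male =`, `female =`) of cohort
#'   CSVs to read instead of simulating.
#' @param seed Master integer seed; all stage seeds derive from it.
#' @param engines Character subset of `c("framingham", "ascvd")`.
#' @param outcome_mode `"engine_true_risk"` (truth = the male Framingham
#'   coefficients for both sexes, emulating a population whose female risk
#'   follows the male equation) or `"subtype_hazards"`.
#' @param transfer Run the male-coefficients-on-female-data experiment?
#' @param search_pool Term-group pool for the data-driven search (NULL
#'   skips the search stage); see [default_term_pool()].
#' @param folds Cross-validation folds for the search.
#' @param bins,hl_variant Calibration options passed to [hosmer_lemeshow()].
#' @param out_dir Optional directory; when set, predictions, reports,
#'   decile tables, the importance table and a run log are written there.
#' @return A `run_config` list.
#' @export
run_config <- function(n_male = 5000, n_female = 5000, cohort_paths = NULL,
                       seed = 1L, engines = c("framingham", "ascvd"),
                       outcome_mode = c("engine_true_risk", "subtype_hazards"),
                       transfer = TRUE, search_pool = NULL, folds = 5,
                       bins = 10, hl_variant = "hosmer-lemeshow",
                       out_dir = NULL) {
  outcome_mode <- match.arg(outcome_mode)
  stopifnot(all(engines %in% c("framingham", "ascvd")), length(engines) >= 1)
  stopifnot(seed == as.integer(seed))
  if (!is.null(cohort_paths)) {
    stopifnot(all(file.exists(unlist(cohort_paths))))
  }
  structure(
    list(
      n_male = n_male, n_female = n_female, cohort_paths = cohort_paths,
      seed = as.integer(seed), engines = engines, outcome_mode = outcome_mode,
      transfer = transfer, search_pool = search_pool, folds = folds,
      bins = bins, hl_variant = hl_variant, out_dir = out_dir
    ),
    class = "run_config"
  )
}

pipeline_cohort <- function(config, sex) {
  if (!is.null(config$cohort_paths)) {
    return(read_cohort(config$cohort_paths[[sex]]))
  }
  n <- if (sex == "male") config$n_male else config$n_female
  seed <- config$seed + if (sex == "male") 100L else 200L
  cov <- generate_covariates(n, sex = sex, seed = seed)
  ospec <- if (config$outcome_mode == "engine_true_risk") {
    outcome_spec("engine_true_risk", engine = builtin_spec("framingham", "male"))
  } else {
    outcome_spec("subtype_hazards")
  }
  simulate_outcomes(cov, ospec, seed = seed + 1L)
}

#' Run the full evaluation pipeline
#'
#' Stages, in order: cohort assembly (synthetic or from file), exclusion
#' cascade, engine age-eligibility, scoring with each engine's own-sex
#' coefficients, discrimination/calibration reports, the paired DeLong
#' comparison between engines, the male-to-female coefficient-transfer
#' experiment, the data-driven Cox subset search, and leave-one-term-out
#' variance-importance tables for every model. Deterministic given the
#' config seed.
#'
#' @param config A [run_config()].
#' @return A named list bundle: `cohorts`, `exclusion_logs`, `predictions`,
#'   `evaluations`, `delong`, `transfer`, `search`, `importance`,
#'   `seed_manifest`. Written to `config$out_dir` when set.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  sexes <- c("male", "female")
  cohorts <- list()
  exclusion_logs <- list()
  for (sex in sexes) {
    raw <- pipeline_cohort(config, sex)
    filtered <- apply_exclusions(raw)
    cohorts[[sex]] <- filtered
    exclusion_logs[[sex]] <- exclusion_log(filtered)
  }

  predictions <- list()
  evaluations <- list()
  for (engine in config$engines) {
    for (sex in sexes) {
      eligible <- engine_eligibility(cohorts[[sex]], engine)
      spec <- builtin_spec(engine, sex)
      pred <- dplyr::bind_cols(
        predict_risk(eligible, spec),
        tibble::tibble(event = as.logical(eligible$event))
      )
      key <- paste(engine, sex, sep = "_")
      predictions[[key]] <- pred
      evaluations[[key]] <- evaluate_predictions(
        pred, bins = config$bins, variant = config$hl_variant
      )
    }
  }

  delong <- list()
  if (all(c("framingham", "ascvd") %in% config$engines)) {
    for (sex in sexes) {
      # paired comparison on the intersection of the two eligibility windows
      both <- engine_eligibility(engine_eligibility(cohorts[[sex]], "framingham"), "ascvd")
      fr <- predict_risk(both, builtin_spec("framingham", sex))$risk
      av <- predict_risk(both, builtin_spec("ascvd", sex))$risk
      delong[[sex]] <- delong_test(fr, av, as.logical(both$event))
    }
  }

  transfer <- NULL
  if (isTRUE(config$transfer) && "framingham" %in% config$engines) {
    eligible <- engine_eligibility(cohorts$female, "framingham")
    male_spec <- transfer_spec(builtin_spec("framingham", "male"), "female")
    female_spec <- builtin_spec("framingham", "female")
    pred_m <- predict_risk(eligible, male_spec)$risk
    pred_f <- predict_risk(eligible, female_spec)$risk
    labels <- as.logical(eligible$event)
    transfer <- list(
      original = list(
        roc = roc_auc(pred_f, labels),
        calibration = hosmer_lemeshow(pred_f, labels, bins = config$bins,
                                      variant = config$hl_variant)
      ),
      transferred = list(
        roc = roc_auc(pred_m, labels),
        calibration = hosmer_lemeshow(pred_m, labels, bins = config$bins,
                                      variant = config$hl_variant)
      ),
      delong = delong_test(pred_m, pred_f, labels)
    )
  }

  search <- NULL
  if (!is.null(config$search_pool)) {
    search <- purrr::map(setNames(sexes, sexes), function(sex) {
      cv_subset_search(
        cohorts[[sex]], pool = config$search_pool,
        folds = config$folds, seed = config$seed + 300L
      )
    })
  }

  importance <- purrr::map_dfr(config$engines, function(engine) {
    purrr::map_dfr(sexes, function(sex) {
      variance_importance(builtin_spec(engine, sex), cohorts[[sex]])
    })
  })
  if (!is.null(search)) {
    importance <- dplyr::bind_rows(
      importance,
      purrr::map_dfr(sexes, function(sex) {
        variance_importance(search[[sex]]$final_fit, cohorts[[sex]])
      })
    )
  }

  bundle <- list(
    cohorts = cohorts,
    exclusion_logs = exclusion_logs,
    predictions = predictions,
    evaluations = evaluations,
    delong = delong,
    transfer = transfer,
    search = search,
    importance = importance,
    seed_manifest = list(
      master = config$seed,
      cohort_male = config$seed + 100L, cohort_female = config$seed + 200L,
      search = config$seed + 300L
    )
  )
  if (!is.null(config$out_dir)) write_bundle(bundle, config)
  bundle
}

write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(config$out_dir, ...)
  for (key in names(bundle$predictions)) {
    readr::write_csv(bundle$predictions[[key]], path(paste0("predictions_", key, ".csv")))
  }
  for (key in names(bundle$evaluations)) {
    ev <- bundle$evaluations[[key]]
    readr::write_csv(tidy(ev$calibration), path(paste0("deciles_", key, ".csv")))
  }
  report <- list(
    seed_manifest = bundle$seed_manifest,
    exclusion_logs = purrr::map(bundle$exclusion_logs, as.list),
    evaluations = purrr::map(bundle$evaluations, function(ev) {
      list(roc = as.list(tidy(ev$roc)), calibration = as.list(glance(ev$calibration)))
    }),
    delong = purrr::map(bundle$delong, function(d) as.list(tidy(d))),
    transfer = if (is.null(bundle$transfer)) NULL else list(
      original = list(
        roc = as.list(tidy(bundle$transfer$original$roc)),
        calibration = as.list(glance(bundle$transfer$original$calibration))
      ),
      transferred = list(
        roc = as.list(tidy(bundle$transfer$transferred$roc)),
        calibration = as.list(glance(bundle$transfer$transferred$calibration))
      ),
      delong = as.list(tidy(bundle$transfer$delong))
    ),
    search = if (is.null(bundle$search)) NULL else
      purrr::map(bundle$search, function(s) as.list(glance(s)))
  )
  jsonlite::write_json(report, path("report.json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(bundle$importance, path("importance.csv"))
  writeLines(
    c(
      sprintf("riskbench %s", as.character(utils::packageVersion("riskbench"))),
      sprintf("R %s", getRversion()),
      sprintf("master seed %d", bundle$seed_manifest$master),
      sprintf("stage counts: %s", paste(
        names(bundle$cohorts),
        vapply(bundle$cohorts, nrow, integer(1)), sep = "=", collapse = ", "
      ))
    ),
    path("run_log.txt")
  )
  invisible(config$out_dir)
}
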