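# Exhaustive covariate-subset search under cross-validated AUC, and the
# leave-one-term-out variance-importance statistic.

#' Default candidate term pool for the data-driven model
#'
#' The engine covariates (log age squared, log total cholesterol, log HDL,
#' the treated/untreated log-SBP pair, smoking, diabetes) plus log BMI,
#' log LDL, log triglycerides and log fasting glucose as additional
#' predictors. Each pool entry is a named list of one or more
#' [risk_term()]s; grouped entries (the SBP pair) enter or leave a subset
#' together.
#'
#' @return A named list of term groups.
#' @export
default_term_pool <- function() {
  list(
    ln_age_square = list(risk_term("ln_age_square", "age", "ln_square", 0)),
    ln_total_cholesterol = list(risk_term("ln_total_cholesterol", "total_cholesterol", "ln", 0)),
    ln_hdl = list(risk_term("ln_hdl", "hdl", "ln", 0)),
    sbp = list(
      risk_term("ln_sbp_treated", "sbp", "ln", 0, "bp_treated", 1),
      risk_term("ln_sbp_untreated", "sbp", "ln", 0, "bp_treated", 0)
    ),
    smoker = list(risk_term("smoker", "smoker", "identity", 0)),
    diabetes = list(risk_term("diabetes", "diabetes", "identity", 0)),
    ln_bmi = list(risk_term("ln_bmi", "bmi", "ln", 0)),
    ln_ldl = list(risk_term("ln_ldl", "ldl", "ln", 0)),
    ln_triglycerides = list(risk_term("ln_triglycerides", "triglycerides", "ln", 0)),
    ln_fasting_glucose = list(risk_term("ln_fasting_glucose", "fasting_glucose", "ln", 0))
  )
}

# Normalize a pool: plain risk_terms become singleton groups.
normalize_pool <- function(pool) {
  if (inherits(pool, "risk_term")) pool <- list(pool)
  pool <- purrr::map(pool, function(entry) {
    if (inherits(entry, "risk_term")) list(entry) else entry
  })
  if (is.null(names(pool)) || any(!nzchar(names(pool)))) {
    names(pool) <- purrr::map_chr(pool, function(g) g[[1]]$name)
  }
  pool
}

# Event-stratified fold assignment, deterministic given the seed.
assign_folds <- function(events, folds, seed) {
  withr::with_seed(seed, {
    fold <- integer(length(events))
    for (cls in unique(events)) {
      idx <- sample(which(events == cls))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

#' Exhaustive covariate-subset search under cross-validated AUC
#'
#' Evaluates every non-empty subset of the candidate pool: for each
#' subset, a Cox model is fitted on each training split of an
#' event-stratified k-fold partition, held-out records are scored with the
#' fit's 10-year risk `1 - S0^exp(L - mean_lp)`, and one AUC is computed
#' over the pooled out-of-fold predictions. The winner is the subset with
#' the highest cross-validated AUC (ties towards smaller, then earlier,
#' subsets), refitted on the full cohort.
#'
#' @param cohort A validated cohort.
#' @param pool A named list of term groups (see [default_term_pool()]).
#' @param folds Number of cross-validation folds, default 5.
#' @param seed Integer seed controlling fold assignment.
#' @param force Evaluate pools larger than 20 groups anyway (2^20 subsets).
#' @return A `model_search_result`: `subsets` tibble (one row per subset
#'   with its CV AUC), `best_subset`, `per_fold_auc` for the winner,
#'   `cv_auc`, and `final_fit` (a `cox_fit` on all data).
#' @export
cv_subset_search <- function(cohort, pool = default_term_pool(), folds = 5,
                             seed = 1L, force = FALSE) {
  pool <- normalize_pool(pool)
  if (length(pool) == 0) abort("`pool` must be non-empty")
  if (length(pool) > 20 && !force) {
    abort("pool larger than 20 groups: 2^|pool| subsets; pass force = TRUE to proceed")
  }
  cohort <- validate_cohort(cohort)
  ev <- as.logical(cohort$event)
  fold <- assign_folds(ev, folds, seed)
  if (any(tapply(ev, fold, sum) == 0)) {
    abort("a fold has no events; reduce `folds` or enlarge the cohort")
  }
  p <- length(pool)
  subset_idx <- unlist(
    lapply(seq_len(p), function(k) combn(p, k, simplify = FALSE)),
    recursive = FALSE
  )
  score_subset <- function(idx) {
    terms <- unlist(pool[idx], recursive = FALSE)
    preds <- numeric(nrow(cohort))
    fold_auc <- numeric(folds)
    for (f in seq_len(folds)) {
      test <- fold == f
      fit <- fit_cox(cohort[!test, , drop = FALSE], terms)
      spec <- as_engine_spec(fit)
      preds[test] <- predict_risk(cohort[test, , drop = FALSE], spec)$risk
      fold_auc[f] <- placements(preds[test], ev[test])$auc
    }
    list(auc = placements(preds, ev)$auc, fold_auc = fold_auc)
  }
  scored <- purrr::map(subset_idx, score_subset)
  aucs <- purrr::map_dbl(scored, "auc")
  sizes <- lengths(subset_idx)
  # ties: smaller subset first, then enumeration (lexicographic) order
  ord <- order(-aucs, sizes, seq_along(subset_idx))
  best <- ord[1]
  winner_terms <- unlist(pool[subset_idx[[best]]], recursive = FALSE)
  final_fit <- fit_cox(cohort, winner_terms)
  structure(
    list(
      pool = names(pool),
      subsets = tibble::tibble(
        subset = purrr::map_chr(subset_idx, function(i) paste(names(pool)[i], collapse = "+")),
        size = sizes,
        cv_auc = aucs
      ),
      n_subsets = length(subset_idx),
      best_subset = names(pool)[subset_idx[[best]]],
      per_fold_auc = scored[[best]]$fold_auc,
      cv_auc = aucs[best],
      folds = folds, seed = seed,
      final_fit = final_fit
    ),
    class = "model_search_result"
  )
}

#' @export
print.model_search_result <- function(x, ...) {
  cat(sprintf(
    "<model_search_result> %d subsets over {%s}; best = {%s}, CV AUC = %.4f\n",
    x$n_subsets, paste(x$pool, collapse = ", "),
    paste(x$best_subset, collapse = ", "), x$cv_auc
  ))
  invisible(x)
}

#' @export
tidy.model_search_result <- function(x, ...) tidy(x$final_fit)

#' @export
glance.model_search_result <- function(x, ...) {
  tibble::tibble(
    n_subsets = x$n_subsets,
    best_subset = paste(x$best_subset, collapse = "+"),
    cv_auc = x$cv_auc,
    min_fold_auc = min(x$per_fold_auc),
    max_fold_auc = max(x$per_fold_auc),
    folds = x$folds
  )
}

#' Leave-one-term-out variance importance
#'
#' With `L` the model's linear predictor over the cohort and `L_-j` the
#' predictor with term j's contribution removed (all coefficients
#' unchanged), the importance of term j is
#' `100 * (Var(L) - Var(L_-j)) / Var(L)`. Under correlated covariates
#' shares can be negative and need not sum to 100; they are reported as
#' computed. Conditional term pairs (treated/untreated SBP) are reported
#' as separate rows.
#'
#' @param object A `risk_engine_spec` or `cox_fit`.
#' @param cohort A data frame of participant records.
#' @return An `importance_table` tibble with columns `term` and
#'   `variance_share` (percent), plus `model` and `sex` attributes carried
#'   as columns.
#' @export
variance_importance <- function(object, cohort) {
  UseMethod("variance_importance")
}

#' @export
variance_importance.risk_engine_spec <- function(object, cohort) {
  importance_core(object$terms, cohort, model = object$engine, sex = object$sex)
}

#' @export
variance_importance.cox_fit <- function(object, cohort) {
  importance_core(object$terms, cohort, model = "data-driven", sex = unique(cohort$sex)[1])
}

importance_core <- function(terms, cohort, model, sex) {
  if (nrow(cohort) == 0) abort("`cohort` must be non-empty")
  contrib <- term_matrix(cohort, terms)
  l_full <- rowSums(contrib)
  v_full <- var(l_full)
  if (!is.finite(v_full) || v_full <= 0) {
    abort("degenerate model: the linear predictor has zero variance")
  }
  share <- vapply(seq_along(terms), function(j) {
    100 * (v_full - var(l_full - contrib[, j])) / v_full
  }, numeric(1))
  tibble::tibble(
    model = model, sex = sex,
    term = names(terms), variance_share = share
  )
}
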