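# End-to-end validation pipeline: recode -> (impute) -> predict all models ->
# calibration / discrimination -> count-matched classification -> decision
# curves, assembled into one machine-readable report.

validate_one <- function(predictions, outcomes, comparator_flags, grid,
                         n_calibration_groups = 10) {
  y <- outcomes
  a <- auc(predictions, y)
  cal <- calibration_intercept_slope(predictions, y)
  groups <- calibration_groups(predictions, y, n_calibration_groups)
  crit <- sens_spec(comparator_flags, y)
  matched <- match_threshold_to_count(predictions, sum(comparator_flags))
  model_ss <- suppressWarnings(
    sens_spec(predictions >= matched$threshold, y,
              threshold = matched$threshold))
  rng <- positive_nb_range(predictions, y, comparator_flags, grid)
  list(auc = a, calibration = cal, calibration_groups = groups,
       criteria_classification = crit, matched_threshold = matched,
       model_classification = model_ss, positive_nb_range = rng)
}

#' Run the full model-validation pipeline on one cohort
#'
#' Applies implausible-value recoding, optionally multiple imputation, then
#' evaluates every requested risk model against the outcomes: AUC (DeLong
#' CI), calibration intercept/slope and grouped calibration data, the
#' criteria-based comparator's sensitivity/specificity, each model's
#' count-matched threshold and classification at it, and the
#' positive-net-benefit threshold range versus the comparator. Under
#' multiple imputation, AUCs are pooled on the logit scale and calibration
#' statistics on the raw scale by Rubin's rules; net-benefit differences are
#' averaged across imputations before range detection.
#'
#' @param subjects cohort data.frame.
#' @param outcomes outcomes data.frame (`id`, `lc_incidence`, `lc_death`).
#' @param models model ids (default all nine).
#' @param outcome_type `"incidence"` or `"death"`.
#' @param horizon 5 or 6 (years).
#' @param imputation `NULL` for complete-case, or
#'   `list(m = , iterations = , seed = )`.
#' @param completed optional list of pre-completed cohorts (e.g. from
#'   [impute_mice()] plus [impute_with_donor()]); overrides `imputation`.
#' @param grid decision-curve threshold grid.
#' @param seed seed recorded in the report and used for imputation when
#'   `imputation$seed` is absent.
#' @return `validation_report` (list; serializable via
#'   [write_validation_report()]).
#' @export
run_validation <- function(subjects, outcomes, models = MODEL_IDS,
                           outcome_type = c("incidence", "death"),
                           horizon = 6, imputation = NULL, completed = NULL,
                           grid = seq(0.001, 0.200, by = 0.001), seed = 1) {
  outcome_type <- match.arg(outcome_type)
  rec <- recode_implausible(subjects)
  subjects <- rec$subjects
  outcomes <- outcomes[match(subjects$id, outcomes$id), ]
  y <- if (outcome_type == "incidence") outcomes$lc_incidence
       else outcomes$lc_death

  if (is.null(completed)) {
    completed <- if (is.null(imputation)) {
      list(subjects)
    } else {
      impute_mice(subjects, m = imputation$m %||% 20,
                  iterations = imputation$iterations %||% 10,
                  seed = imputation$seed %||% seed)
    }
  }

  per_model <- lapply(models, function(m) {
    per_imp <- lapply(completed, function(dat) {
      pred <- predict_risk(dat, m, horizon)
      comp <- nlst_eligible(dat)
      comp[is.na(comp)] <- FALSE
      p <- pmin(pmax(pred$probability, 1e-10), 1 - 1e-10)
      validate_one(p, y, comp, grid)
    })
    if (length(per_imp) == 1) {
      res <- per_imp[[1]]
      res$pooled <- FALSE
      res
    } else {
      aucs <- vapply(per_imp, function(r) r$auc$auc, numeric(1))
      auc_ses <- vapply(per_imp, function(r) r$auc$se, numeric(1))
      pooled_auc <- pool_transformed(pmin(pmax(aucs, 1e-8), 1 - 1e-8),
                                     auc_ses, "logit")
      slopes <- vapply(per_imp, function(r) r$calibration$slope, numeric(1))
      slope_ses <- vapply(per_imp, function(r) r$calibration$slope_se,
                          numeric(1))
      ints <- vapply(per_imp, function(r) r$calibration$intercept, numeric(1))
      int_ses <- vapply(per_imp, function(r) r$calibration$intercept_se,
                        numeric(1))
      res <- per_imp[[1]]
      res$pooled <- TRUE
      res$auc_pooled <- pooled_auc
      res$calibration_pooled <- list(
        slope = pool_transformed(slopes, slope_ses, "identity"),
        intercept = pool_transformed(ints, int_ses, "identity"))
      res
    }
  })
  names(per_model) <- models

  structure(list(
    outcome_type = outcome_type, horizon = horizon,
    n = nrow(subjects), n_events = sum(y),
    models = per_model,
    recode_log = rec$log,
    imputation = if (is.null(imputation)) NULL else
      list(m = imputation$m %||% 20,
           iterations = imputation$iterations %||% 10),
    seed = seed), class = "validation_report")
}

#' Serialize a validation report to JSON
#'
#' @param report from [run_validation()].
#' @param path output path.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  invisible(path)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report: %s, %d-y horizon, n = %d (%d events)\n",
              x$outcome_type, x$horizon, x$n, x$n_events))
  for (m in names(x$models)) {
    r <- x$models[[m]]
    cat(sprintf("  %-22s AUC %.3f  slope %.2f  matched sens %.1f%% (criteria %.1f%%)\n",
                m, r$auc$auc, r$calibration$slope,
                100 * r$model_classification$sensitivity,
                100 * r$criteria_classification$sensitivity))
  }
  invisible(x)
}
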