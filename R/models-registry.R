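# Model registry: config-driven absolute-risk models behind one interface.
#
# Each model is described by a YAML payload (structure + coefficients) shipped
# under inst/extdata/models/. Code carries only the model *structure*; the
# numeric payloads live in the config files. Payload files whose constants are
# plausibility-calibrated stand-ins (rather than transcriptions of the
# original publications) carry a `_synthetic` filename suffix and a
# `provenance: synthetic` field.

MODEL_IDS <- c("bach", "llp", "llp_simplified", "plcom2012",
               "plcom2012_simplified", "tsce_incidence", "knoke",
               "tsce_cps_death", "tsce_nhs_hpfs_death")

model_config_file <- function(model_id) {
  dir <- system.file("extdata", "models", package = "lcriskval")
  cands <- c(file.path(dir, paste0(model_id, ".yaml")),
             file.path(dir, paste0(model_id, "_synthetic.yaml")))
  hit <- cands[file.exists(cands)]
  if (length(hit) == 0)
    stop(sprintf("model registry error: no config payload for '%s'", model_id),
         call. = FALSE)
  hit[1]
}

.model_cache <- new.env(parent = emptyenv())

#' List the registered risk models
#'
#' @return data.frame with `model_id`, `outcome` (incidence or death),
#'   `horizon` (native prediction time frame, years), `type` (structural
#'   family) and `provenance` (`published` for payloads transcribed from the
#'   original publication, `synthetic` for plausibility-calibrated stand-ins).
#' @export
list_models <- function() {
  rows <- lapply(MODEL_IDS, function(m) {
    cfg <- load_model(m)
    data.frame(model_id = m, outcome = cfg$outcome, horizon = cfg$horizon,
               type = cfg$type, provenance = cfg$provenance %||% "published",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Load a model's coefficient payload
#'
#' @param model_id one of the registered model ids (see [list_models()]).
#' @return the parsed payload (list) with fields `model_id`, `outcome`,
#'   `horizon`, `type`, `covariates` plus structure-specific blocks.
#' @export
load_model <- function(model_id) {
  if (!model_id %in% MODEL_IDS)
    stop(sprintf("model registry error: unknown model_id '%s'", model_id),
         call. = FALSE)
  if (!is.null(.model_cache[[model_id]])) return(.model_cache[[model_id]])
  cfg <- yaml::read_yaml(model_config_file(model_id))
  stopifnot(identical(cfg$model_id, model_id),
            cfg$outcome %in% c("incidence", "death"))
  .model_cache[[model_id]] <- cfg
  cfg
}

require_covariates <- function(subjects, covariates, model_id) {
  for (cv in covariates) {
    if (!cv %in% names(subjects))
      stop(sprintf("incomplete-covariate error: '%s' absent for model %s",
                   cv, model_id), call. = FALSE)
    if (anyNA(subjects[[cv]]))
      stop(sprintf("incomplete-covariate error: '%s' missing for %d subject(s) in model %s (impute first)",
                   cv, sum(is.na(subjects[[cv]])), model_id), call. = FALSE)
  }
  invisible(TRUE)
}

#' Predict absolute lung-cancer risk for a cohort
#'
#' Dispatches to the model-specific engine: the logistic PLCOm2012 family,
#' the odds-ratio LLP family, the annual-cycle Bach/Knoke compositions, or
#' the two-stage clonal expansion hazard solver. Deterministic. Subjects must
#' be complete on the model's covariates (impute first); never-smokers are
#' rejected.
#'
#' Fixed-horizon models (PLCOm2012: 6 y; LLP: 5 y) return their native-frame
#' risk regardless of `horizon`, used unchanged as scores; iterative models
#' compose annual cycles to the requested horizon.
#'
#' @param subjects cohort data.frame (complete on the model's covariates).
#' @param model_id registered model id, or a payload list from [load_model()].
#' @param horizon prediction horizon in years (5 or 6).
#' @return data.frame with `id`, `model_id`, `outcome`, `horizon`,
#'   `probability` (one row per subject).
#' @export
predict_risk <- function(subjects, model_id, horizon = 6) {
  if (!horizon %in% c(1, 5, 6))
    stop("horizon must be 1, 5 or 6 years", call. = FALSE)
  cfg <- if (is.list(model_id)) model_id else load_model(model_id)
  if (any(!is.na(subjects$smoking_status) & subjects$smoking_status == "never"))
    stop("never-smokers must be excluded before model evaluation", call. = FALSE)
  require_covariates(subjects, cfg$covariates, cfg$model_id)

  p <- switch(cfg$type,
    logistic = plogis(logistic_linear_predictor(cfg, subjects)),
    llp_odds = llp_risk(subjects, cfg),
    annual_cycle = annual_cycle_risk(subjects, cfg, horizon),
    tsce = tsce_model_risk(subjects, cfg, horizon),
    stop(sprintf("unknown model type '%s'", cfg$type), call. = FALSE))

  eff_horizon <- if (cfg$type %in% c("annual_cycle", "tsce")) horizon else cfg$horizon
  stopifnot(all(p >= 0 & p <= 1))
  data.frame(id = subjects$id, model_id = cfg$model_id, outcome = cfg$outcome,
             horizon = eff_horizon, probability = p, stringsAsFactors = FALSE)
}

#' Predict with every requested model
#'
#' @param subjects cohort data.frame.
#' @param models character vector of model ids (default: all nine).
#' @param horizon years (5 or 6).
#' @return long data.frame of per-model [predict_risk()] results.
#' @export
predict_cohort <- function(subjects, models = MODEL_IDS, horizon = 6) {
  do.call(rbind, lapply(models, function(m) predict_risk(subjects, m, horizon)))
}
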