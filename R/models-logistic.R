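# Logistic-form absolute-risk models (PLCOm2012 family).
#
# The PLCOm2012 model is a logistic regression for 6-y lung cancer incidence
# among ever-smokers: intercept + sum of coefficient x (centered/transformed
# covariate), including a reciprocal-power transform of smoking intensity and
# race/ethnicity category weights. The payload mirrors the published
# coefficient table (Tammemagi et al., NEJM 2013).

#' Linear predictor (log-odds) of a logistic-payload model
#'
#' Exposed so that the centering identity (all covariates at their centering
#' constants and indicators at reference give the intercept) and coefficient
#' differences can be checked directly on the log-odds scale.
#'
#' @param cfg payload list (see [load_model()]), `type: logistic`.
#' @param subjects cohort data.frame, complete on the payload's covariates.
#' @return numeric vector of log-odds.
#' @export
logistic_linear_predictor <- function(cfg, subjects) {
  lp <- rep(cfg$intercept, nrow(subjects))
  tm <- cfg$terms

  add_linear <- function(lp, field, term) {
    if (is.null(term)) return(lp)
    centre <- term$center %||% 0
    lp + term$coef * (subjects[[field]] - centre)
  }
  lp <- add_linear(lp, "age", tm$age)
  lp <- add_linear(lp, "education", tm$education)
  lp <- add_linear(lp, "bmi", tm$bmi)
  lp <- add_linear(lp, "smoking_duration", tm$smoking_duration)
  lp <- add_linear(lp, "years_since_quit", tm$years_since_quit)

  add_indicator <- function(lp, x, term) {
    if (is.null(term)) return(lp)
    lp + term$coef * as.numeric(x)
  }
  lp <- add_indicator(lp, subjects$copd, tm$copd)
  lp <- add_indicator(lp, subjects$personal_history_cancer,
                      tm$personal_history_cancer)
  lp <- add_indicator(lp, subjects$family_history_lc, tm$family_history_lc)
  lp <- add_indicator(lp, subjects$smoking_status == "current",
                      tm$smoking_status_current)

  it <- tm$intensity_transform
  if (!is.null(it)) {
    x <- subjects$smoking_intensity
    if (any(x <= 0))
      stop("domain error: smoking intensity must be positive for the ",
           "reciprocal-power intensity transform", call. = FALSE)
    lp <- lp + it$coef * ((x / it$divisor)^it$power - it$center)
  }
  if (!is.null(cfg$race_coefs)) {
    rc <- unlist(cfg$race_coefs)
    lp <- lp + rc[subjects$race]
  }
  unname(lp)
}
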