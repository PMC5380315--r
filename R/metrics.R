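# Validation metrics: calibration (grouped plot data, intercept, slope),
# discrimination (AUC with DeLong CI), sensitivity/specificity with Wilson
# CIs, and count-matched threshold selection.

#' Grouped calibration-plot data
#'
#' Groups subjects into (by default decile) bins of predicted risk and
#' returns, per group, the mean predicted risk, the observed event
#' proportion and the group size. If fewer distinct predictions exist than
#' requested groups, the group count is reduced with a warning.
#'
#' @param predictions predicted probabilities in (0, 1).
#' @param outcomes logical (or 0/1) observed events.
#' @param n_groups number of quantile groups (default 10).
#' @return data.frame `mean_predicted`, `observed_proportion`, `n`; group
#'   sizes sum to the cohort size.
#' @export
calibration_groups <- function(predictions, outcomes, n_groups = 10) {
  check_prob_open(predictions)
  stopifnot(length(predictions) == length(outcomes))
  outcomes <- as.numeric(outcomes)
  breaks <- unique(stats::quantile(predictions,
                                   probs = seq(0, 1, length.out = n_groups + 1)))
  if (length(breaks) - 1 < n_groups)
    warning(sprintf("reduced calibration groups from %d to %d (tied predictions)",
                    n_groups, max(length(breaks) - 1, 1)))
  if (length(breaks) == 1) breaks <- c(breaks - 1e-12, breaks + 1e-12)
  grp <- cut(predictions, breaks, include.lowest = TRUE)
  agg <- data.frame(
    mean_predicted = tapply(predictions, grp, mean),
    observed_proportion = tapply(outcomes, grp, mean),
    n = as.integer(table(grp)))
  rownames(agg) <- NULL
  agg[agg$n > 0, , drop = FALSE]
}

#' Calibration intercept and slope
#'
#' The calibration slope is the coefficient of `logit(prediction)` in a
#' logistic regression of the outcome on the predictions' log-odds; the
#' calibration intercept (calibration-in-the-large) is the intercept of a
#' logistic fit with `logit(prediction)` as a fixed-coefficient-1 offset.
#' Perfect predictions give (0, 1); slope < 1 indicates over-dispersed
#' predictions.
#'
#' The unconstrained fit's intercept (`slope_intercept`) is also returned: for
#' outcomes generated from a logit-scale distortion `a + b * logit(p)` it
#' estimates `a` directly, whereas the offset-based calibration intercept
#' equals `a` only when `b = 1`.
#'
#' @inheritParams calibration_groups
#' @return list `intercept`, `slope`, `slope_intercept`, standard errors
#'   `intercept_se`, `slope_se`, and a `separation` flag (estimates unbounded
#'   when TRUE).
#' @export
calibration_intercept_slope <- function(predictions, outcomes) {
  check_prob_open(predictions)
  outcomes <- as.numeric(outcomes)
  if (length(unique(outcomes)) < 2)
    stop("both outcome classes must be present", call. = FALSE)
  lp <- stats::qlogis(predictions)
  slope_fit <- suppressWarnings(
    stats::glm(outcomes ~ lp, family = stats::binomial()))
  int_fit <- suppressWarnings(
    stats::glm(outcomes ~ 1 + offset(lp), family = stats::binomial()))
  sep <- !slope_fit$converged || !int_fit$converged ||
    max(abs(stats::coef(slope_fit))) > 20
  list(intercept = unname(stats::coef(int_fit)[1]),
       slope = unname(stats::coef(slope_fit)[2]),
       slope_intercept = unname(stats::coef(slope_fit)[1]),
       intercept_se = unname(sqrt(diag(stats::vcov(int_fit))[1])),
       slope_se = unname(sqrt(diag(stats::vcov(slope_fit))[2])),
       separation = sep)
}

#' Area under the ROC curve with DeLong confidence interval
#'
#' Concordance probability with ties counted 1/2 (midrank estimator); the
#' confidence interval uses the DeLong placement-value variance.
#'
#' @param scores risk scores (any monotone scale).
#' @param outcomes logical (or 0/1) events; both classes must be present.
#' @param level confidence level (default 0.95).
#' @return list `auc`, `ci_lower`, `ci_upper`, `se`, `n_cases`, `n_controls`.
#' @export
auc <- function(scores, outcomes, level = 0.95) {
  outcomes <- as.logical(outcomes)
  n1 <- sum(outcomes)
  n0 <- sum(!outcomes)
  if (n1 == 0 || n0 == 0)
    stop("undefined AUC: one outcome class is absent", call. = FALSE)
  r <- rank(scores)                        # midranks handle ties as 1/2
  est <- (sum(r[outcomes]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # DeLong: placement values of cases among controls and vice versa
  cases <- scores[outcomes]
  controls <- scores[!outcomes]
  v10 <- vapply(cases, function(s)
    (sum(s > controls) + 0.5 * sum(s == controls)) / n0, numeric(1))
  v01 <- vapply(controls, function(s)
    (sum(cases > s) + 0.5 * sum(cases == s)) / n1, numeric(1))
  se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = est, ci_lower = max(0, est - z * se),
       ci_upper = min(1, est + z * se), se = se,
       n_cases = n1, n_controls = n0)
}

#' Sensitivity and specificity of an eligibility strategy
#'
#' Sensitivity is the number of individuals with the outcome classified as
#' eligible divided by all individuals with the outcome; specificity the
#' number without the outcome classified ineligible divided by all without
#' the outcome. 95% Wilson score intervals.
#'
#' @param eligible_flags logical classification (TRUE = screen).
#' @param outcomes logical events.
#' @param threshold optional threshold annotation carried into the result.
#' @return list with counts `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, their `ci`s, and `threshold`.
#' @export
sens_spec <- function(eligible_flags, outcomes, threshold = NA_real_) {
  stopifnot(length(eligible_flags) == length(outcomes))
  e <- as.logical(eligible_flags)
  y <- as.logical(outcomes)
  tp <- sum(e & y); fp <- sum(e & !y); fn <- sum(!e & y); tn <- sum(!e & !y)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  if (tp + fn == 0) warning("no cases: sensitivity undefined")
  if (tn + fp == 0) warning("no non-cases: specificity undefined")
  list(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = sens, specificity = spec,
       sensitivity_ci = wilson_ci(tp, tp + fn),
       specificity_ci = wilson_ci(tn, tn + fp))
}

#' Risk threshold matching a target selected count
#'
#' The threshold at which classifying `prediction >= threshold` as eligible
#' selects (up to ties) `n_target` individuals: the `n_target`-th largest
#' prediction. With ties, all tied individuals are included and the realized
#' count (possibly above `n_target`) is reported.
#'
#' @param predictions predicted risks.
#' @param n_target target number selected (1..length(predictions)).
#' @return list `threshold`, `n_target`, `realized_count`, `ties` (flag).
#' @export
match_threshold_to_count <- function(predictions, n_target) {
  n <- length(predictions)
  if (n_target < 1 || n_target > n)
    stop("n_target out of range", call. = FALSE)
  thr <- sort(predictions, decreasing = TRUE)[n_target]
  realized <- sum(predictions >= thr)
  if (realized > n_target)
    warning(sprintf("ties at the matched threshold: realized count %d > target %d",
                    realized, n_target))
  list(threshold = thr, n_target = as.integer(n_target),
       realized_count = as.integer(realized), ties = realized > n_target)
}
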