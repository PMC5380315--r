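# Decision-curve analysis: net benefit, threshold odds / harm ratio,
# decision curves against criteria-based strategies, and positive-net-benefit
# threshold ranges.
#
# Net benefit of a strategy at risk threshold t:
#
#   NB(t) = ( TP - FP * t/(1-t) ) / n
#
# where TP counts eligible individuals with the event and FP eligible
# individuals without it. The weighting factor t/(1-t) is the threshold odds;
# its reciprocal (1-t)/t — the harm ratio — expresses how much worse missing
# one detectable case is valued than unnecessarily screening one person.
# Both framings are exposed as distinct functions to prevent reciprocal
# confusion.

#' Threshold odds (net-benefit weighting factor)
#'
#' @param t risk threshold in (0, 1).
#' @return `t / (1 - t)`.
#' @examples
#' threshold_odds(0.025)  # 1/39
#' @export
threshold_odds <- function(t) {
  if (any(t <= 0 | t >= 1))
    stop("domain error: risk threshold must lie in (0, 1)", call. = FALSE)
  t / (1 - t)
}

#' Harm ratio at a risk threshold
#'
#' The reciprocal of the threshold odds, `(1 - t) / t`: at threshold 2.5%,
#' missing one detectable lung cancer is valued 39 times worse than one
#' unnecessary screen (equivalently, one case should be detected per 40
#' persons screened). Reported to one decimal when tabulated.
#'
#' @param t risk threshold in (0, 1).
#' @return `(1 - t) / t`.
#' @examples
#' harm_ratio(0.025)  # 39
#' @export
harm_ratio <- function(t) {
  1 / threshold_odds(t)
}

#' Net benefit of an eligibility strategy at one threshold
#'
#' @param eligible_flags logical classification (TRUE = screen). Use
#'   `predictions >= t` for a model strategy, an external criteria flag for a
#'   comparator, all-TRUE for screen-all and all-FALSE for screen-none.
#' @param outcomes logical events.
#' @param t risk threshold in (0, 1).
#' @return list `threshold`, `tp`, `fp`, `n`, `net_benefit`.
#' @export
net_benefit <- function(eligible_flags, outcomes, t) {
  stopifnot(length(eligible_flags) == length(outcomes))
  n <- length(outcomes)
  if (n == 0) stop("empty cohort", call. = FALSE)
  threshold_odds(t)  # domain check
  e <- as.logical(eligible_flags)
  y <- as.logical(outcomes)
  tp <- sum(e & y)
  fp <- sum(e & !y)
  list(threshold = t, tp = tp, fp = fp, n = n,
       net_benefit = (tp - fp * threshold_odds(t)) / n)
}

#' Decision curve over a grid of risk thresholds
#'
#' Computes net benefit per threshold for the model strategy (eligibility
#' re-evaluated as `predictions >= t` at each threshold), an optional
#' criteria-based comparator (fixed flags), screen-all and screen-none.
#'
#' @param predictions predicted risks.
#' @param outcomes logical events.
#' @param comparator_flags logical criteria-based eligibility, or `NULL`.
#' @param grid sorted thresholds within (0, 1); default 0.1%-20% by 0.1%.
#' @return data.frame `threshold`, `strategy`, `tp`, `fp`, `n`, `net_benefit`.
#' @export
decision_curve <- function(predictions, outcomes, comparator_flags = NULL,
                           grid = seq(0.001, 0.200, by = 0.001)) {
  stopifnot(!is.unsorted(grid))
  strategies <- list(
    model = function(t) predictions >= t,
    screen_all = function(t) rep(TRUE, length(outcomes)),
    screen_none = function(t) rep(FALSE, length(outcomes)))
  if (!is.null(comparator_flags))
    strategies$comparator <- function(t) comparator_flags
  rows <- lapply(grid, function(t) {
    do.call(rbind, lapply(names(strategies), function(s) {
      nb <- net_benefit(strategies[[s]](t), outcomes, t)
      data.frame(threshold = t, strategy = s, tp = nb$tp, fp = nb$fp,
                 n = nb$n, net_benefit = nb$net_benefit,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Threshold range with positive net benefit over a comparator
#'
#' The lowest and highest grid thresholds at which the model strategy's net
#' benefit strictly exceeds the comparator's. An empty range is represented
#' by `NA` bounds.
#'
#' @inheritParams decision_curve
#' @param comparator_flags logical criteria-based eligibility.
#' @return list `lower`, `upper` (thresholds, or `NA`), `n_positive` (grid
#'   points with a strictly positive difference), `grid_step`.
#' @export
positive_nb_range <- function(predictions, outcomes, comparator_flags,
                              grid = seq(0.001, 0.200, by = 0.001)) {
  dc <- decision_curve(predictions, outcomes, comparator_flags, grid)
  model <- dc[dc$strategy == "model", ]
  comp <- dc[dc$strategy == "comparator", ]
  pos <- model$net_benefit > comp$net_benefit
  if (!any(pos))
    return(list(lower = NA_real_, upper = NA_real_, n_positive = 0L,
                grid_step = stats::median(diff(grid))))
  list(lower = min(grid[pos]), upper = max(grid[pos]),
       n_positive = as.integer(sum(pos)),
       grid_step = stats::median(diff(grid)))
}

#' Interpret a net-benefit difference
#'
#' A net-benefit difference `delta_nb` at threshold `t` is equivalent to
#' `delta_nb * 1000` additional true positives per 1,000 persons assessed, or
#' `delta_nb * 1000 / (t/(1-t))` fewer false positives per 1,000 assessed.
#'
#' @param delta_nb net-benefit difference between two strategies.
#' @param t risk threshold in (0, 1).
#' @return list `tp_gain_per_1000`, `fp_reduction_per_1000`.
#' @examples
#' interpret_nb_delta(0.002, 0.025)  # 2 TP gained, 78 FP avoided
#' @export
interpret_nb_delta <- function(delta_nb, t) {
  w <- threshold_odds(t)
  list(tp_gain_per_1000 = delta_nb * 1000,
       fp_reduction_per_1000 = delta_nb * 1000 / w)
}
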