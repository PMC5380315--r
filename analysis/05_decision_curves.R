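#!/usr/bin/env Rscript
# Stage 5 — decision-curve analysis against the pack-year criteria.
#
# For each model on the completed PLCO-like cohort: the decision curve
# (model / criteria comparator / screen-all / screen-none), the threshold
# range with positive net benefit over the criteria, and the sensitivity/
# specificity comparison at the count-matched threshold, written as
# plot-ready CSVs.

library(lcriskval)

dir.create("results/dca", showWarnings = FALSE, recursive = TRUE)

coh <- read_cohort("results/imputed/plco_like_imp01.csv")$subjects
outcomes <- read_cohort("results/cohorts/plco_like.csv")$outcomes
y <- outcomes$lc_incidence[match(coh$id, outcomes$id)]
crit <- nlst_eligible(coh)
cs <- sens_spec(crit, y)
grid <- seq(0.001, 0.200, by = 0.001)

preds <- read_cohort("results/imputed/plco_like_imp01.csv")  # ids aligned
preds <- predict_cohort(coh, horizon = 6)

curves <- list(); ranges <- list(); matched <- list()
for (m in unique(preds$model_id)) {
  p <- preds$probability[preds$model_id == m]
  dc <- decision_curve(p, y, crit, grid)
  dc$model_id <- m
  curves[[m]] <- dc
  rng <- positive_nb_range(p, y, crit, grid)
  ranges[[m]] <- data.frame(
    model_id = m, lower_pct = 100 * rng$lower, upper_pct = 100 * rng$upper,
    lower_harm_ratio = round(harm_ratio(rng$lower), 1),
    upper_harm_ratio = round(harm_ratio(rng$upper), 1))
  mt <- suppressWarnings(match_threshold_to_count(p, sum(crit)))
  ms <- suppressWarnings(sens_spec(p >= mt$threshold, y, mt$threshold))
  matched[[m]] <- data.frame(
    model_id = m, threshold_pct = 100 * mt$threshold,
    selected = mt$realized_count,
    sensitivity_pct = 100 * ms$sensitivity,
    specificity_pct = 100 * ms$specificity)
}

utils::write.csv(do.call(rbind, curves), "results/dca/decision_curves.csv",
                 row.names = FALSE)
utils::write.csv(do.call(rbind, ranges), "results/dca/positive_nb_ranges.csv",
                 row.names = FALSE)
cmp <- rbind(
  data.frame(model_id = "pack_year_criteria", threshold_pct = NA,
             selected = sum(crit), sensitivity_pct = 100 * cs$sensitivity,
             specificity_pct = 100 * cs$specificity),
  do.call(rbind, matched))
utils::write.csv(cmp, "results/dca/matched_count_comparison.csv",
                 row.names = FALSE)
cat("sensitivity/specificity at matched selected counts:\n")
print(cmp, row.names = FALSE, digits = 3)
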