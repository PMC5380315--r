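#!/usr/bin/env Rscript
# Stage 3 — absolute-risk predictions.
#
# Runs all nine risk models on the first completed PLCO-like cohort and on
# the NLST-like cohort, writes the long prediction tables, and prints the
# spread of model risks for a fixed worked-example profile (the point being
# that the same person's absolute risk varies substantially between models).

library(lcriskval)

dir.create("results/predictions", showWarnings = FALSE, recursive = TRUE)

plco <- read_cohort("results/imputed/plco_like_imp01.csv")$subjects
nlst <- read_cohort("results/cohorts/nlst_like.csv")$subjects

for (nm in c("plco", "nlst")) {
  coh <- get(nm)
  preds <- predict_cohort(coh, horizon = 6)
  utils::write.csv(preds, sprintf("results/predictions/%s_predictions.csv", nm),
                   row.names = FALSE)
}

example <- data.frame(
  id = "example", age = 70, gender = "male", race = "white", education = 2,
  bmi = 28, copd = TRUE, emphysema = FALSE, personal_history_cancer = FALSE,
  family_history_lc = TRUE, history_pneumonia = FALSE, asbestos = FALSE,
  smoking_status = "current", smoking_duration = 55, smoking_intensity = 30,
  years_since_quit = 0, pack_years = 82.5, stringsAsFactors = FALSE)
spread <- predict_cohort(example)
utils::write.csv(spread, "results/predictions/example_profile_risks.csv",
                 row.names = FALSE)
cat("6-y risk spread for one 70-y current smoker (30/day for 55 y):\n")
print(spread[order(-spread$probability), c("model_id", "outcome", "probability")],
      row.names = FALSE, digits = 3)
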