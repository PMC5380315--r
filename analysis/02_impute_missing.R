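#!/usr/bin/env Rscript
# Stage 2 — multiple imputation.
#
# Fills the PLCO-like cohort's missing cells by chained equations (m
# imputations) after donor-imputing the wholly unmeasured pneumonia history
# from the NLST-like cohort, and writes one completed CSV per imputation.

library(lcriskval)

seed <- 20260920
m <- 5          # imputations carried through the workflow
dir.create("results/imputed", showWarnings = FALSE, recursive = TRUE)

plco <- read_cohort("results/cohorts/plco_like.csv")
nlst <- read_cohort("results/cohorts/nlst_like.csv")

# donor predictors must be complete: impute the donor's own holes first (none
# by construction) and the target's predictor holes within each chain below;
# the donor transfer uses the complete-case rows of the target
target <- plco$subjects
chains <- impute_mice(target[setdiff(names(target), "history_pneumonia")],
                      m = m, iterations = 5, seed = seed + 10)
completed <- lapply(seq_len(m), function(i) {
  filled <- chains[[i]]
  filled$history_pneumonia <- NA
  donor_fill <- impute_with_donor(filled, nlst$subjects, "history_pneumonia",
                                  m = 1, seed = seed + 20 + i)[[1]]
  donor_fill
})

for (i in seq_len(m)) {
  write_cohort(completed[[i]],
               sprintf("results/imputed/plco_like_imp%02d.csv", i))
}
rates <- vapply(completed[[1]], function(x) mean(is.na(x)), numeric(1))
stopifnot(all(rates == 0))
cat(sprintf("wrote %d completed cohorts (n = %d), pneumonia prevalence %.1f%% (donor %.1f%%)\n",
            m, nrow(target),
            100 * mean(completed[[1]]$history_pneumonia),
            100 * mean(nlst$subjects$history_pneumonia)))
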