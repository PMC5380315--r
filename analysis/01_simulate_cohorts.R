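#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohorts.
#
# Generates an NLST-like heavy-smoker cohort (eligible by construction) and a
# broader PLCO-like ever-smoker cohort, simulates 6-y lung-cancer incidence
# and death from the PLCOm2012 model, and injects questionnaire-like
# missingness into the PLCO-like cohort. Everything downstream reads the
# CSVs written here.

library(lcriskval)

seed <- 20260920
n_plco <- 20000
n_nlst <- 10000
dir.create("results/cohorts", showWarnings = FALSE, recursive = TRUE)

nlst <- generate_cohort(cohort_scenario("nlst_like", n_nlst), seed = seed)
plco <- generate_cohort(cohort_scenario("plco_like", n_plco), seed = seed + 1)

out_nlst <- simulate_outcomes(nlst, "plcom2012", seed = seed + 2)
out_plco <- simulate_outcomes(plco, "plcom2012", seed = seed + 3)

prof <- missingness_profile("trial_like")
plco_missing <- inject_missingness(plco, prof$rates, "MCAR", rho = prof$rho,
                                   seed = seed + 4)
# pneumonia history is unmeasured in the PLCO-like cohort; the NLST-like
# cohort serves as its imputation donor downstream
plco_missing$history_pneumonia <- NA

write_cohort(nlst, "results/cohorts/nlst_like.csv",
             out_nlst[c("id", "lc_incidence", "lc_death", "horizon")])
write_cohort(plco_missing, "results/cohorts/plco_like.csv",
             out_plco[c("id", "lc_incidence", "lc_death", "horizon")])

cat(sprintf("NLST-like: n = %d, eligible %.1f%%, 6-y incidence %.2f%%\n",
            n_nlst, 100 * mean(nlst_eligible(nlst)),
            100 * mean(out_nlst$lc_incidence)))
cc_fields <- setdiff(names(prof$rates), "history_pneumonia")
cat(sprintf("PLCO-like: n = %d, complete cases %.1f%% (pneumonia unmeasured), 6-y incidence %.2f%%\n",
            n_plco, 100 * complete_case_fraction(plco_missing, cc_fields),
            100 * mean(out_plco$lc_incidence)))
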