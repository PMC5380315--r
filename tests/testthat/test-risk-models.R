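test_that("registry lists nine models with matching outcomes and horizons", {
  lm_ <- list_models()
  expect_equal(nrow(lm_), 9)
  expect_setequal(lm_$model_id[lm_$outcome == "death"],
                  c("knoke", "tsce_cps_death", "tsce_nhs_hpfs_death"))
  expect_equal(lm_$horizon[lm_$model_id == "plcom2012"], 6)
  expect_equal(lm_$horizon[lm_$model_id == "llp"], 5)
  expect_error(load_model("nonexistent"), "registry")
})

test_that("missing covariates raise explicit incomplete-covariate errors", {
  s <- make_subject(bmi = NA)
  expect_error(predict_risk(s, "plcom2012"), "incomplete-covariate.*bmi")
  expect_silent(predict_risk(s, "knoke"))  # bmi not a Knoke covariate
  expect_error(predict_risk(make_subject(smoking_status = "never",
                                         years_since_quit = 1), "knoke"),
               "never-smokers")
})

test_that("PLCOm2012 reproduces an independent hand computation", {
  # worked profile: 63-y black woman, college graduate (level 5), former
  # smoker (quit 10 y) of 15 cigs/day for 40 y, BMI 25, no comorbidities
  s <- example_profiles()[2, ]
  lp <- -4.532506 +
    0.0778868 * (63 - 62) +
    0.3944778 +                               # black
    -0.0812744 * (5 - 4) +
    -0.0274194 * (25 - 27) +
    0.0317321 * (40 - 27.6017) +
    -0.0308572 * (10 - 8.593417) +
    -1.822606 * ((15 / 10)^-1 - 0.4021541613)
  expect_equal(logistic_linear_predictor(load_model("plcom2012"), s), lp,
               tolerance = 1e-12)
  expect_equal(predict_risk(s, "plcom2012")$probability, plogis(lp),
               tolerance = 1e-12)

  # heavy-smoker worked profile: 70-y white male, high-school graduate,
  # 30/day for 55 y, current, BMI 28, COPD, family history
  s1 <- example_profiles()[1, ]
  lp1 <- -4.532506 + 0.0778868 * 8 - 0.0812744 * (2 - 4) -
    0.0274194 * (28 - 27) + 0.3553063 + 0.587185 + 0.2597431 +
    0.0317321 * (55 - 27.6017) - 0.0308572 * (0 - 8.593417) -
    1.822606 * ((30 / 10)^-1 - 0.4021541613)
  expect_equal(predict_risk(s1, "plcom2012")$probability, plogis(lp1),
               tolerance = 1e-12)
})

test_that("logistic centering identity and coefficient differences hold", {
  cfg <- load_model("plcom2012")
  s <- make_subject(age = 62, race = "white", education = 4, bmi = 27,
                    smoking_status = "former",
                    smoking_duration = 27.6017,
                    years_since_quit = 8.593417,
                    smoking_intensity = 10 / 0.4021541613)
  expect_equal(logistic_linear_predictor(cfg, s), cfg$intercept,
               tolerance = 1e-12)

  a <- make_subject(copd = FALSE)
  b <- make_subject(copd = TRUE)
  expect_equal(logistic_linear_predictor(cfg, b) -
               logistic_linear_predictor(cfg, a),
               cfg$terms$copd$coef, tolerance = 1e-12)
  expect_error(predict_risk(make_subject(smoking_intensity = 0), "plcom2012"),
               "domain")
})

test_that("annual-cycle composition matches hand arithmetic", {
  s <- make_subject()
  # constant toy payload: p_lc = 0.01, p_death = 0.05, two cycles
  two <- predict_risk(s, toy_cycle_payload(0.01, 0.05), horizon = 1)
  expect_equal(two$probability, 0.01, tolerance = 1e-12)    # base case
  cfg <- toy_cycle_payload(0.01, 0.05)
  # 0.01 + 0.99 * 0.95 * 0.01
  expect_equal(lcriskval:::annual_cycle_risk(s, cfg, 2), 0.019405,
               tolerance = 1e-12)

  # zero competing death: risk = 1 - (1 - p)^h
  cfg0 <- toy_cycle_payload(0.01)
  expect_equal(lcriskval:::annual_cycle_risk(s, cfg0, 6),
               1 - 0.99^6, tolerance = 1e-12)
  # zero-hazard payload
  expect_equal(predict_risk(s, toy_cycle_payload(0), horizon = 6)$probability, 0)
})

test_that("Knoke model composes yearly death hazards over the horizon", {
  s <- make_subject(smoking_status = "former", years_since_quit = 5,
                    smoking_duration = 35)
  cfg <- load_model("knoke")
  # independent evaluation of the published-form composition on a yearly grid
  p_year <- function(age, dur, quit) {
    lp <- cfg$lc_hazard$intercept +
      cfg$lc_hazard$age * (age - cfg$lc_hazard$age_center) +
      cfg$lc_hazard$duration * dur +
      cfg$lc_hazard$log_intensity * log1p(s$smoking_intensity) +
      cfg$lc_hazard$quit_years * quit
    1 - exp(-exp(lp))
  }
  surv <- 1
  risk <- 0
  for (k in 0:5) {
    pk <- p_year(62 + k, 35, 5 + k)     # former: duration frozen, quit advances
    risk <- risk + surv * pk
    surv <- surv * (1 - pk)
  }
  expect_equal(predict_risk(s, "knoke", 6)$probability, risk,
               tolerance = 1e-12)
  expect_equal(predict_risk(s, "knoke", 1)$probability, p_year(62, 35, 5),
               tolerance = 1e-12)
})

test_that("LLP reduces to the age-sex baseline at reference levels", {
  cfg <- load_model("llp")
  s <- make_subject(age = 65, gender = "male", smoking_status = "former",
                    smoking_duration = 0.5, years_since_quit = 10,
                    asbestos = NA)
  # all ORs at reference: risk equals the payload's age-sex baseline
  mins <- vapply(cfg$baseline_risk$bands, function(b) b$min, numeric(1))
  base <- cfg$baseline_risk$bands[[max(which(mins <= 65))]]$male
  expect_equal(predict_risk(s, "llp")$probability, base, tolerance = 1e-12)
  # moving duration up one category strictly increases risk
  risks <- vapply(c(10, 30, 50, 65), function(d)
    predict_risk(make_subject(smoking_status = "former", smoking_duration = d,
                              years_since_quit = 5, age = 75),
                 "llp")$probability, numeric(1))
  expect_true(all(diff(risks) > 0))
})

test_that("risks lie in [0,1] and are monotone in smoking exposure", {
  prof <- random_profiles(40, seed = 11)
  for (m in c("plcom2012", "plcom2012_simplified", "llp", "llp_simplified",
              "bach", "knoke", "tsce_incidence", "tsce_cps_death",
              "tsce_nhs_hpfs_death")) {
    p0 <- predict_risk(prof, m, 6)$probability
    expect_true(all(p0 >= 0 & p0 <= 1), info = m)

    longer <- prof
    longer$smoking_duration <- prof$smoking_duration + 3
    longer$age <- prof$age + 3   # keep start age fixed, duration < age
    longer$pack_years <- pack_years(longer$smoking_duration,
                                    longer$smoking_intensity)
    base_aged <- prof
    base_aged$age <- prof$age + 3
    if (m != "llp" && m != "llp_simplified") {
      # duration increase at fixed age for regression-style models
      longer2 <- prof
      longer2$smoking_duration <- pmin(prof$smoking_duration + 3,
                                       prof$age - prof$years_since_quit - 1)
      longer2$pack_years <- pack_years(longer2$smoking_duration,
                                       longer2$smoking_intensity)
      p_longer <- predict_risk(longer2, m, 6)$probability
      expect_true(all(p_longer >= p0 - 1e-12), info = paste(m, "duration"))
    }

    heavier <- prof
    heavier$smoking_intensity <- prof$smoking_intensity + 10
    heavier$pack_years <- pack_years(heavier$smoking_duration,
                                     heavier$smoking_intensity)
    expect_true(all(predict_risk(heavier, m, 6)$probability >= p0 - 1e-12),
                info = paste(m, "intensity"))

    former <- prof[prof$smoking_status == "former", ]
    if (nrow(former) > 0) {
      p_f <- predict_risk(former, m, 6)$probability
      later <- former
      later$years_since_quit <- former$years_since_quit - 1
      later$smoking_duration <- former$smoking_duration + 1
      later$pack_years <- pack_years(later$smoking_duration,
                                     later$smoking_intensity)
      # quitting later (shorter abstinence, longer smoking) never lowers risk
      expect_true(all(predict_risk(later, m, 6)$probability >= p_f - 1e-12),
                  info = paste(m, "quit"))
    }
  }
})

test_that("iterative models are horizon-consistent: risk(6) >= risk(5) >= risk(1)", {
  prof <- random_profiles(20, seed = 3)
  for (m in c("bach", "knoke", "tsce_incidence", "tsce_cps_death",
              "tsce_nhs_hpfs_death")) {
    r6 <- predict_risk(prof, m, 6)$probability
    r5 <- predict_risk(prof, m, 5)$probability
    r1 <- predict_risk(prof, m, 1)$probability
    expect_true(all(r6 >= r5 & r5 >= r1), info = m)
  }
})

test_that("different models give different absolute risks for one subject", {
  s <- example_profiles()[1, ]
  risks <- predict_cohort(s)$probability
  expect_gt(length(unique(round(risks, 6))), 5)
  # simplified and full PLCOm2012 generally differ
  expect_false(isTRUE(all.equal(
    predict_risk(s, "plcom2012")$probability,
    predict_risk(s, "plcom2012_simplified")$probability)))
})
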