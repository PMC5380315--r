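test_that("a complete cohort imputes to identical copies", {
  coh <- generate_cohort(cohort_scenario("plco_like", 200), seed = 8)
  out <- impute_mice(coh, m = 2, iterations = 1, seed = 1)
  expect_length(out, 2)
  expect_identical(out[[1]], coh)
  expect_identical(out[[2]], coh)
})

test_that("imputation is seed-reproducible and never touches observed cells", {
  coh <- generate_cohort(cohort_scenario("plco_like", 800), seed = 3)
  pr <- missingness_profile()
  holey <- inject_missingness(coh, pr$rates, "MCAR", rho = pr$rho, seed = 5)
  a <- impute_mice(holey, m = 2, iterations = 2, seed = 42)
  b <- impute_mice(holey, m = 2, iterations = 2, seed = 42)
  expect_identical(a, b)
  c_ <- impute_mice(holey, m = 2, iterations = 2, seed = 43)
  expect_false(identical(a, c_))

  for (v in names(pr$rates)) {
    obs <- !is.na(holey[[v]])
    expect_identical(a[[1]][[v]][obs], holey[[v]][obs], info = v)
    expect_false(anyNA(a[[1]][[v]]))
  }
  # structural zero: current smokers never get imputed quit-years
  cur <- holey$smoking_status == "current" & !is.na(holey$smoking_status)
  expect_true(all(a[[1]]$years_since_quit[cur] == 0))
  # type domains respected
  expect_true(all(a[[1]]$bmi >= 14 & a[[1]]$bmi <= 60))
  expect_true(all(a[[1]]$education %in% 1:6))
})

test_that("MCAR imputation recovers the complete-data association", {
  # binary variable with a strong observed predictor, 20% MCAR
  set.seed(7)
  n <- 4000
  coh <- generate_cohort(cohort_scenario("plco_like", n), seed = 21)
  lp <- -2 + 0.08 * (coh$pack_years - 30) / 10 * 10 / 8   # depends on pack-years
  coh$copd <- runif(n) < plogis(-2 + 0.06 * (coh$pack_years - 30))
  full_fit <- glm(copd ~ pack_years, binomial, data = coh)

  holey <- coh
  drop_idx <- sample(n, 0.2 * n)
  holey$copd[drop_idx] <- NA
  imps <- impute_mice(holey, m = 5, iterations = 3, seed = 9)
  coefs <- vapply(imps, function(d)
    coef(glm(copd ~ pack_years, binomial, data = d))[2], numeric(1))
  ses <- vapply(imps, function(d)
    summary(glm(copd ~ pack_years, binomial, data = d))$coefficients[2, 2],
    numeric(1))
  pooled <- rubin_pool(coefs, ses^2)
  full_coef <- coef(full_fit)[2]
  expect_lt(abs(pooled$q_bar - full_coef), 4 * sqrt(pooled$t_var))
})

test_that("an all-missing variable requires donor imputation", {
  coh <- generate_cohort(cohort_scenario("plco_like", 100), seed = 2)
  coh$history_pneumonia <- NA
  expect_error(impute_mice(coh, m = 2, seed = 1), "donor")
})

test_that("donor imputation recovers a deterministic rule and degenerate donors", {
  donor <- generate_cohort(cohort_scenario("nlst_like", 1500), seed = 4)
  target <- generate_cohort(cohort_scenario("plco_like", 1000), seed = 5)
  target$history_pneumonia <- NA

  # plant a separable deterministic rule in the donor
  donor$history_pneumonia <- donor$age >= 61
  imps <- impute_with_donor(target, donor, "history_pneumonia", m = 3, seed = 6)
  agree <- vapply(imps, function(d)
    mean(d$history_pneumonia == (d$age >= 61)), numeric(1))
  expect_true(all(agree >= 0.99))

  donor$history_pneumonia <- TRUE
  const <- impute_with_donor(target, donor, "history_pneumonia", m = 2, seed = 1)
  expect_true(all(const[[1]]$history_pneumonia))

  expect_error(impute_with_donor(target, donor[0, ], "history_pneumonia"),
               "empty donor")
})

test_that("Rubin pooling matches hand-computed values", {
  # degenerate: identical estimates => no between-imputation variance
  p0 <- rubin_pool(rep(0.70, 5), rep(0.01, 5))
  expect_equal(p0$q_bar, 0.70)
  expect_equal(p0$b, 0)
  expect_equal(p0$t_var, 0.01)
  expect_equal(p0$df, Inf)

  # m = 2 toy: b = var(0.6, 0.8) = 0.02, t = 0.01 + 1.5 * 0.02 = 0.04
  p1 <- rubin_pool(c(0.6, 0.8), c(0.01, 0.01))
  expect_equal(p1$q_bar, 0.7)
  expect_equal(p1$b, 0.02, tolerance = 1e-12)
  expect_equal(p1$t_var, 0.04, tolerance = 1e-12)
  expect_gte(p1$t_var, p1$u_bar)

  # scaling estimates by c scales q_bar by c and t_var by c^2
  p2 <- rubin_pool(3 * c(0.6, 0.8), 9 * c(0.01, 0.01))
  expect_equal(p2$q_bar, 3 * p1$q_bar)
  expect_equal(p2$t_var, 9 * p1$t_var, tolerance = 1e-12)

  expect_error(rubin_pool(0.5, 0.01), "m >= 2")
})

test_that("pooled interval widens with between-imputation variance", {
  tight <- rubin_pool(c(0.69, 0.71, 0.70), rep(0.01, 3))
  wide <- rubin_pool(c(0.55, 0.85, 0.70), rep(0.01, 3))
  expect_gt(diff(wide$ci), diff(tight$ci))
})

test_that("low missingness reproduces complete-case metrics", {
  coh <- generate_cohort(cohort_scenario("plco_like", 6000), seed = 31)
  out <- simulate_outcomes(coh, "plcom2012", seed = 32)
  full_auc <- auc(predict_risk(coh, "plcom2012")$probability,
                  out$lc_incidence)$auc

  rates <- c(bmi = 0.01, family_history_lc = 0.01, smoking_duration = 0.01)
  holey <- inject_missingness(coh, rates, "MCAR", seed = 33)
  imps <- impute_mice(holey, m = 3, iterations = 2, seed = 34)
  aucs <- vapply(imps, function(d)
    auc(predict_risk(d, "plcom2012")$probability, out$lc_incidence)$auc,
    numeric(1))
  expect_lt(abs(mean(aucs) - full_auc), 0.01)
})
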