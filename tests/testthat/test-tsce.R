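const_params <- function(nu = 0.1, alpha = 0, beta = 0, mu = 0.05, lag = 0,
                         dose_response = NULL) {
  list(nu = nu, alpha = alpha, beta = beta, mu = mu, lag = lag,
       dose_response = dose_response)
}
no_dose <- data.frame(t_start = 0, t_end = Inf, dose = 0)

test_that("smoking_schedule encodes the three exposure segments", {
  s1 <- smoking_schedule(70, 55, 30, 0)     # started at 15, still smoking
  expect_equal(s1$t_start, c(0, 15))
  expect_equal(s1$t_end, c(15, Inf))
  expect_equal(s1$dose, c(0, 30))

  s2 <- smoking_schedule(63, 40, 15, 10)    # 13 -> 53, quit at 53
  expect_equal(s2$t_start, c(0, 13, 53))
  expect_equal(s2$t_end, c(13, 53, Inf))
  expect_equal(s2$dose, c(0, 15, 0))

  expect_error(smoking_schedule(50, 45, 20, 10), "start age")
})

test_that("degenerate rates give survival one", {
  sched <- smoking_schedule(70, 55, 30, 0)
  expect_equal(tsce_survival(const_params(mu = 0, alpha = 1, beta = 0.9),
                             sched, 0, 80), 1)
  expect_equal(tsce_survival(const_params(nu = 0), sched, 0, 80), 1)
  expect_equal(tsce_hazard(const_params(mu = 0, alpha = 1, beta = 0.9),
                           sched, 50), 0)
})

test_that("no-expansion limit matches its closed form to 1e-6", {
  p <- const_params(nu = 0.1, alpha = 0, beta = 0, mu = 0.05)
  for (t in c(5, 10, 20, 40, 70)) {
    expect_equal(tsce_survival(p, no_dose, 0, t),
                 exp(-0.1 * (t - (1 - exp(-0.05 * t)) / 0.05)),
                 tolerance = 1e-10)
    expect_equal(tsce_hazard(p, no_dose, t), 0.1 * (1 - exp(-0.05 * t)),
                 tolerance = 1e-6)
  }
})

test_that("survival is a proper non-increasing semigroup", {
  p <- const_params(nu = 0.2, alpha = 1.2, beta = 1.0, mu = 1e-4, lag = 3)
  sched <- smoking_schedule(70, 40, 25, 10)
  ts <- seq(0, 80, by = 5)
  S <- vapply(ts, function(t) tsce_survival(p, sched, 0, t), numeric(1))
  expect_true(all(diff(S) <= 1e-12))
  expect_true(all(S > 0 & S <= 1))

  # semigroup: S(a2)/S(a0) = S(a1)/S(a0) * S(a2)/S(a1)
  for (ages in list(c(0, 30, 60), c(20, 45, 70), c(10, 15, 78))) {
    lhs <- tsce_survival(p, sched, ages[1], ages[3])
    rhs <- tsce_survival(p, sched, ages[1], ages[2]) *
           tsce_survival(p, sched, ages[2], ages[3])
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("interval risk equals composed annual-cycle risks", {
  p <- const_params(nu = 0.3, alpha = 2, beta = 1.9, mu = 1e-5, lag = 5)
  sched <- smoking_schedule(62, 45, 30, 0)
  one <- tsce_risk(p, sched, 62, 6)
  surv <- 1
  for (k in 0:5) surv <- surv * (1 - tsce_risk(p, sched, 62 + k, 1))
  expect_equal(one, 1 - surv, tolerance = 1e-9)
  expect_equal(tsce_risk(p, sched, 62, 0), 0)
})

test_that("pointwise-higher dose never lowers risk", {
  cfg <- load_model("tsce_incidence")
  p <- cfg$params$male
  for (d in c(5, 15, 30, 60)) {
    r_lo <- tsce_risk(p, smoking_schedule(65, 40, d, 5), 65, 6)
    r_hi <- tsce_risk(p, smoking_schedule(65, 40, d + 10, 5), 65, 6)
    expect_gte(r_hi, r_lo)
  }
})

test_that("closed-form solution agrees with adaptive ODE integration to 1e-8", {
  skip_if_not_installed("deSolve")
  set.seed(91)
  for (rep in 1:6) {
    p <- const_params(nu = runif(1, 0.05, 0.4),
                      alpha = runif(1, 0.5, 3),
                      beta = NA, mu = 10^runif(1, -6, -3),
                      lag = sample(0:5, 1),
                      dose_response = list(
                        nu = list(coef = 0.05, power = 1),
                        growth = list(coef = 0.2, power = 0.5),
                        mu = list(coef = 0.02, power = 1)))
    p$beta <- p$alpha - runif(1, 0.02, 0.12)
    sched <- smoking_schedule(70, 40, 20, 10)
    t_end <- 70 - p$lag

    # backward ODE in time-to-go u: phi' = a phi^2 - R phi + b, H' = nu (1 - phi)
    rates_at <- function(s) {
      dose <- if (s >= 20 && s < 60) 20 else 0
      lcriskval:::tsce_rates_at_dose(p, dose)
    }
    deriv <- function(u, y, parms) {
      r <- rates_at(t_end - u)
      list(c(r$alpha * y[1]^2 - (r$alpha + r$beta + r$mu) * y[1] + r$beta,
             r$nu * (1 - y[1])))
    }
    times <- sort(unique(c(0, t_end - 60, t_end - 20, t_end)))
    sol <- deSolve::lsoda(c(phi = 1, H = 0), times, deriv, NULL,
                          rtol = 1e-12, atol = 1e-14)
    H_ode <- unname(sol[nrow(sol), "H"])
    S_closed <- tsce_survival(p, sched, 0, 70)
    expect_equal(S_closed, exp(-H_ode), tolerance = 1e-8)
  }
})

test_that("Monte Carlo oracle is deterministic and matches the no-expansion closed form", {
  p <- const_params(nu = 0.1, alpha = 0, beta = 0, mu = 0.05)
  a <- tsce_mc_survival(p, no_dose, 400, c(10, 20, 40), seed = 5)
  b <- tsce_mc_survival(p, no_dose, 400, c(10, 20, 40), seed = 5)
  expect_identical(a, b)

  mc <- tsce_mc_survival(p, no_dose, 4000, c(10, 20, 40), seed = 17)
  closed <- exp(-0.1 * (mc$t - (1 - exp(-0.05 * mc$t)) / 0.05))
  expect_true(all(abs(mc$survival - closed) <= 3 * mc$se))

  # mu = 0: every replicate survives
  p0 <- const_params(nu = 0.3, alpha = 0.5, beta = 0.4, mu = 0)
  mc0 <- tsce_mc_survival(p0, no_dose, 200, c(20, 50), seed = 2)
  expect_equal(mc0$survival, c(1, 1))
})

test_that("analytic survival lies within Monte Carlo bands for random small parameter sets", {
  set.seed(2024)
  n_cfg <- 8
  inside <- logical(n_cfg)
  for (i in seq_len(n_cfg)) {
    p <- const_params(nu = runif(1, 0.05, 0.25),
                      alpha = runif(1, 0.1, 0.6),
                      beta = NA, mu = 10^runif(1, -3, -1.5),
                      lag = 0)
    p$beta <- max(p$alpha - runif(1, 0.01, 0.08), 0.01)
    sched <- smoking_schedule(40, 20, 10, 5)
    p$dose_response <- list(nu = list(coef = 0.03, power = 1),
                            growth = list(coef = 0.1, power = 0.5),
                            mu = list(coef = 0.02, power = 1))
    mc <- tsce_mc_survival(p, sched, 3000, 40, seed = 100 + i)
    S <- tsce_survival(p, sched, 0, 40)
    inside[i] <- abs(S - mc$survival) <= stats::qnorm(0.995) *
      max(mc$se, sqrt(S * (1 - S) / 3000))
  }
  # 99% bands: allow at most one excursion among the configurations
  expect_gte(sum(inside), n_cfg - 1)
})
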