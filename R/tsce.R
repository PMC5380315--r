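# Two-stage clonal expansion (TSCE) hazard engine.
#
# Biology: normal cells acquire a first (initiation) event at aggregate rate
# nu(t) [initiated cells per year]; each initiated cell divides at rate
# alpha(t), dies/differentiates at rate beta(t), and undergoes malignant
# transformation at rate mu(t). A fixed lag separates the first malignant
# cell from detected cancer (or death, for the death-calibrated fits).
# Smoking enters through published-style dose-response functions that scale
# (nu, net proliferation alpha - beta, mu) with current cigarettes/day, via a
# piecewise-constant exposure schedule.
#
# Mathematics: let Phi(s; t) be the probability that a single cell initiated
# at time s spawns no malignant cell by time t. Backward in s it satisfies
# the Riccati equation
#
#   dPhi/ds = -(alpha Phi^2 - (alpha+beta+mu) Phi + beta)
#
# with Phi(t; t) = 1, and tumour-free survival is
#
#   S(t) = exp( - int_0^t nu(s) (1 - Phi(s; t)) ds ).
#
# For piecewise-constant parameters each segment has a closed form. With
# u = time-to-go inside a segment, R = alpha+beta+mu, discriminant
# D = sqrt(R^2 - 4 alpha beta) and roots y± = (R ± D) / (2 alpha):
#
#   Phi(u) = (y+ - y- A e^{Du}) / (1 - A e^{Du}),  A = (Phi1 - y+)/(Phi1 - y-)
#   int_0^tau (1 - Phi) du = (1 - y+) tau + log((1 - A e^{D tau})/(1 - A)) / alpha
#
# evaluated in the overflow-safe e^{-D tau} parameterization. The alpha = 0
# segment degenerates to a linear ODE with its own closed form. Survival is
# assembled by propagating Phi backward across segments and summing each
# segment's integral contribution; D > 0 is guaranteed whenever mu > 0.

#' Build a piecewise-constant exposure schedule from a smoking history
#'
#' Segments: dose 0 from birth to start age (= age - duration -
#' years_since_quit), the reported cigarettes/day while smoking, and dose 0
#' after quitting. Current smokers are projected to continue smoking, so
#' their smoking segment is open-ended.
#'
#' @param age current age (years).
#' @param duration years smoked.
#' @param intensity cigarettes per day while smoking.
#' @param years_since_quit years since cessation (0 for current smokers).
#' @return data.frame with columns `t_start`, `t_end`, `dose` (contiguous,
#'   non-overlapping; the last segment is open-ended via `t_end = Inf`).
#' @examples
#' smoking_schedule(70, 55, 30, 0)  # started at 15, still smoking
#' @export
smoking_schedule <- function(age, duration, intensity, years_since_quit = 0) {
  stopifnot(length(age) == 1)
  start_age <- age - duration - years_since_quit
  if (is.na(start_age) || start_age < 0)
    stop("validation error: duration + years_since_quit exceed age ",
         "(negative inferred start age)", call. = FALSE)
  quit_age <- if (years_since_quit > 0) start_age + duration else Inf
  seg <- data.frame(t_start = c(0, start_age, quit_age),
                    t_end = c(start_age, quit_age, Inf),
                    dose = c(0, intensity, 0))
  seg <- seg[seg$t_start < seg$t_end, , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

# dose-response: rate(d) = base * (1 + coef * d^power); monotone in d for
# coef >= 0. Net proliferation is modelled (alpha = beta + growth(d)) so the
# clone expands faster while smoking.
tsce_rates_at_dose <- function(params, dose) {
  dr <- function(block, base) {
    if (is.null(block)) return(rep(base, length(dose)))
    base * (1 + block$coef * dose^(block$power %||% 1))
  }
  nu <- dr(params$dose_response$nu, params$nu)
  mu <- dr(params$dose_response$mu, params$mu)
  growth <- dr(params$dose_response$growth, params$alpha - params$beta)
  list(nu = nu, alpha = params$beta + growth, beta = rep(params$beta,
       length(dose)), mu = mu)
}

# closed-form backward propagation across one constant-parameter segment:
# given Phi at the segment's right edge, return Phi at the left edge and the
# segment's contribution to int nu (1 - Phi) ds. Vectorized over segments.
tsce_segment_step <- function(phi1, tau, nu, alpha, beta, mu) {
  n <- length(phi1)
  phi0 <- numeric(n)
  integral <- numeric(n)

  quad <- alpha > 0 & (mu > 0 | abs(alpha - beta) > 0)
  lin <- alpha == 0
  crit <- alpha > 0 & mu == 0 & alpha == beta   # double root at 1

  if (any(quad)) {
    a <- alpha[quad]; b <- beta[quad]; m <- mu[quad]; p1 <- phi1[quad]
    tq <- tau[quad]
    R <- a + b + m
    D <- sqrt(R^2 - 4 * a * b)
    yp <- (R + D) / (2 * a)
    ym <- (R - D) / (2 * a)
    at_root <- abs(p1 - ym) < 1e-14 | abs(p1 - yp) < 1e-14
    A <- ifelse(at_root, 0, (p1 - yp) / (p1 - ym))
    E <- exp(-D * tq)                       # e^{-D tau}, overflow-safe
    phi0[quad] <- ifelse(at_root, p1, (yp * E - ym * A) / (E - A))
    # log((1 - A e^{D tau})/(1 - A)) = D tau + log((E - A)/(1 - A))
    L <- D * tq + log((E - A) / (1 - A))
    integral[quad] <- nu[quad] *
      ifelse(at_root, (1 - p1) * tq, (1 - yp) * tq + L / a)
  }
  if (any(lin)) {
    b <- beta[lin]; m <- mu[lin]; p1 <- phi1[lin]; tq <- tau[lin]
    k <- b + m
    zero_k <- k == 0
    eq <- b / ifelse(zero_k, 1, k)          # equilibrium beta/(beta+mu)
    phi0[lin] <- ifelse(zero_k, p1, eq + (p1 - eq) * exp(-k * tq))
    integral[lin] <- nu[lin] * ifelse(
      zero_k, (1 - p1) * tq,
      tq * m / k - (p1 - eq) * (1 - exp(-k * tq)) / k)
  }
  if (any(crit)) {
    a <- alpha[crit]; p1 <- phi1[crit]; tq <- tau[crit]
    # dPhi/du = a (Phi - 1)^2  =>  Phi(u) = 1 - (1-p1)/(1 + a u (1-p1))
    d1 <- 1 - p1
    phi0[crit] <- 1 - d1 / (1 + a * tq * d1)
    integral[crit] <- nu[crit] * log1p(a * tq * d1) / a
  }
  list(phi0 = phi0, integral = integral)
}

# cumulative "malignancy hazard" integral H(t) = -log S_mal(t): backward pass
# over the schedule segments intersected with [0, t].
tsce_cumhaz <- function(params, schedule, t) {
  if (t <= 0) return(0)
  seg <- schedule[schedule$t_start < t, , drop = FALSE]
  seg$t_end <- pmin(seg$t_end, t)
  rates <- tsce_rates_at_dose(params, seg$dose)
  phi <- 1
  total <- 0
  for (j in rev(seq_len(nrow(seg)))) {
    step <- tsce_segment_step(phi, seg$t_end[j] - seg$t_start[j],
                              rates$nu[j], rates$alpha[j], rates$beta[j],
                              rates$mu[j])
    phi <- step$phi0
    total <- total + step$integral
  }
  total
}

#' Tumour-free survival under the TSCE model
#'
#' Probability of remaining free of detected cancer from age `a0` to `a1`,
#' given survival to `a0`; the detection lag is applied by evaluating the
#' malignancy process at `t - lag`.
#'
#' @param params list with rates `nu`, `alpha`, `beta`, `mu` (per year),
#'   `lag` (years) and optional `dose_response` blocks
#'   (`nu`/`mu`/`growth`, each `list(coef, power)` scaling the baseline rate
#'   by `1 + coef * dose^power`).
#' @param schedule exposure schedule from [smoking_schedule()].
#' @param a0,a1 ages with `a0 <= a1`.
#' @return survival probability in (0, 1].
#' @export
tsce_survival <- function(params, schedule, a0, a1) {
  stopifnot(a0 <= a1)
  lag <- params$lag %||% 0
  h1 <- tsce_cumhaz(params, schedule, max(a1 - lag, 0))
  h0 <- tsce_cumhaz(params, schedule, max(a0 - lag, 0))
  exp(-(h1 - h0))
}

#' TSCE hazard of detected cancer
#'
#' `h(t) = -d log S / dt`, obtained by central differencing of the
#' closed-form log-survival (step 1e-5 y); continuous within exposure
#' segments.
#'
#' @inheritParams tsce_survival
#' @param t age (years).
#' @param delta finite-difference half-step (years).
#' @return hazard (per year).
#' @export
tsce_hazard <- function(params, schedule, t, delta = 1e-5) {
  lag <- params$lag %||% 0
  tm <- t - lag
  if (tm <= 0) return(0)
  lo <- max(tm - delta, 0)
  hi <- tm + delta
  (tsce_cumhaz(params, schedule, hi) - tsce_cumhaz(params, schedule, lo)) /
    (hi - lo)
}

#' Absolute TSCE risk over a horizon
#'
#' `1 - S(a + horizon)/S(a)` for a subject alive and cancer-free at age `a`.
#' By survival multiplicativity this equals the composition of annual-cycle
#' risks over the horizon.
#'
#' @inheritParams tsce_survival
#' @param current_age age at prediction.
#' @param horizon years ahead.
#' @return probability in \[0, 1).
#' @export
tsce_risk <- function(params, schedule, current_age, horizon) {
  1 - tsce_survival(params, schedule, current_age, current_age + horizon)
}

# vectorized cumulative malignancy-hazard integral over subjects sharing one
# parameter set: every smoking history maps to the same three-segment shape
# (pre-start dose 0, smoking dose d, post-quit dose 0), so the backward
# closed-form propagation runs column-wise across subjects.
tsce_cumhaz_vec <- function(params, start_age, quit_age, dose, t) {
  t <- pmax(t, 0)
  b1 <- pmin(start_age, t)
  b2 <- pmin(quit_age, t)
  tau <- cbind(b1, b2 - b1, t - b2)
  seg_dose <- cbind(0, dose, 0)
  phi <- rep(1, length(t))
  total <- rep(0, length(t))
  for (j in 3:1) {
    rates <- tsce_rates_at_dose(params, seg_dose[, j])
    step <- tsce_segment_step(phi, tau[, j], rates$nu, rates$alpha,
                              rates$beta, rates$mu)
    phi <- step$phi0
    total <- total + step$integral
  }
  total
}

# registry adapter: per-gender parameter payloads, vectorized over subjects
tsce_model_risk <- function(subjects, cfg, horizon) {
  start_age <- subjects$age - subjects$smoking_duration -
    subjects$years_since_quit
  if (any(start_age < 0))
    stop("validation error: duration + years_since_quit exceed age",
         call. = FALSE)
  quit_age <- ifelse(subjects$years_since_quit > 0,
                     start_age + subjects$smoking_duration, Inf)
  risk <- numeric(nrow(subjects))
  for (g in unique(subjects$gender)) {
    i <- subjects$gender == g
    params <- cfg$params[[g]]
    lag <- params$lag %||% 0
    h1 <- tsce_cumhaz_vec(params, start_age[i], quit_age[i],
                          subjects$smoking_intensity[i],
                          subjects$age[i] + horizon - lag)
    h0 <- tsce_cumhaz_vec(params, start_age[i], quit_age[i],
                          subjects$smoking_intensity[i],
                          subjects$age[i] - lag)
    risk[i] <- 1 - exp(-(h1 - h0))
  }
  risk
}
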