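# Synthetic cohort generator.
#
# Emulates the marginal risk-factor structure of the two screening-trial
# populations (an NLST-like heavy-smoker cohort constrained to the pack-year
# eligibility criteria, and a broader PLCO-like ever-smoker cohort) from
# declared parametric families: truncated-normal age, log-normal
# duration/intensity/quit-years tuned to the published medians and IQRs,
# categorical race/education frequencies, and comorbidity probabilities
# logistic in pack-years. Smoking duration is generated through a start-age
# distribution so that it correlates with age; intensity is drawn
# independently given status. Outcomes are simulated from a designated
# generating model with an optional logit-scale calibration distortion.

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

plco_like_params <- function() {
  list(
    name = "plco_like",
    age = list(mean = 62, sd = 5.9, min = 55, max = 74),
    p_male = 0.583,
    race_probs = c(white = 0.883, black = 0.057, hispanic = 0.020,
                   asian = 0.031, pacific_islander = 0.0055,
                   native_american = 0.0035),
    education_probs = c(0.086, 0.222, 0.134, 0.233, 0.166, 0.159),
    bmi = list(meanlog = log(26.68), sdlog = 0.16),
    p_current = 0.194,
    start_age = list(mean = 17, sd = 4, min = 10, max = 35),
    intensity = list(meanlog = log(20), sdlog = 0.60),
    quit_years = list(meanlog = log(20), sdlog = 0.75, max = NA),
    copd = list(intercept = -3.15, slope = 0.02),
    emphysema = list(intercept = -3.90, slope = 0.02),
    p_cancer = 0.046,
    fh = list(intercept = -2.10, slope = 0.003),
    p_pneumonia = 0.221,
    eligibility_constrained = FALSE)
}

nlst_like_params <- function() {
  p <- plco_like_params()
  p$name <- "nlst_like"
  p$age <- list(mean = 61, sd = 5.2, min = 55, max = 74)
  p$p_male <- 0.590
  p$race_probs <- c(white = 0.896, black = 0.0444, hispanic = 0.0131,
                    asian = 0.0211, pacific_islander = 0.0034,
                    native_american = 0.0033)
  p$education_probs <- c(0.060, 0.233, 0.140, 0.232, 0.170, 0.143)
  p$bmi <- list(meanlog = log(27.32), sdlog = 0.15)
  p$p_current <- 0.474
  p$intensity <- list(meanlog = log(25), sdlog = 0.41)
  p$quit_years <- list(meanlog = log(7), sdlog = 0.85, max = 15)
  p$copd <- list(intercept = -2.70, slope = 0.02)
  p$emphysema <- list(intercept = -3.70, slope = 0.02)
  p$p_cancer <- 0.043
  p$fh <- list(intercept = -1.50, slope = 0.003)
  p$eligibility_constrained <- TRUE
  p
}

#' Describe a synthetic cohort scenario
#'
#' @param name `"plco_like"` (broad ever-smoker cohort) or `"nlst_like"`
#'   (heavy-smoker cohort satisfying the pack-year eligibility criteria by
#'   construction, ages 55-74).
#' @param n cohort size.
#' @param overrides named list replacing individual scenario parameters.
#' @return scenario object (list) for [generate_cohort()].
#' @export
cohort_scenario <- function(name = c("plco_like", "nlst_like"), n = 10000,
                            overrides = list()) {
  name <- match.arg(name)
  p <- if (name == "plco_like") plco_like_params() else nlst_like_params()
  p[names(overrides)] <- overrides
  p$n <- n
  p
}

draw_subjects <- function(p, n) {
  age <- rtrunc_norm(n, p$age$mean, p$age$sd, p$age$min, p$age$max)
  gender <- ifelse(stats::runif(n) < p$p_male, "male", "female")
  race <- sample(names(p$race_probs), n, replace = TRUE,
                 prob = p$race_probs / sum(p$race_probs))
  education <- sample(1:6, n, replace = TRUE,
                      prob = p$education_probs / sum(p$education_probs))
  bmi <- round(stats::rlnorm(n, p$bmi$meanlog, p$bmi$sdlog), 1)

  current <- stats::runif(n) < p$p_current
  start_age <- rtrunc_norm(n, p$start_age$mean, p$start_age$sd,
                           p$start_age$min, p$start_age$max)
  start_age <- pmin(start_age, age - 5)
  intensity <- pmax(round(stats::rlnorm(n, p$intensity$meanlog,
                                        p$intensity$sdlog)), 1)
  quit <- numeric(n)
  nf <- sum(!current)
  if (nf > 0) {
    q <- stats::rlnorm(nf, p$quit_years$meanlog, p$quit_years$sdlog)
    if (!is.na(p$quit_years$max)) q <- pmin(q, p$quit_years$max - 0.1)
    quit[!current] <- pmin(q, (age - start_age - 3)[!current])
    quit[!current] <- pmax(quit[!current], 0.5)
  }
  duration <- pmax(age - start_age - quit, 1)

  age_f <- floor(age)
  duration <- round(pmin(duration, age_f - 6), 1)
  quit <- round(quit, 1)
  py <- pack_years(duration, intensity)
  data.frame(
    id = NA_character_,
    age = age_f,
    gender = gender, race = race, education = education, bmi = bmi,
    copd = stats::runif(n) < stats::plogis(p$copd$intercept +
                                           p$copd$slope * py),
    emphysema = stats::runif(n) < stats::plogis(p$emphysema$intercept +
                                                p$emphysema$slope * py),
    personal_history_cancer = stats::runif(n) < p$p_cancer,
    family_history_lc = stats::runif(n) < stats::plogis(p$fh$intercept +
                                                        p$fh$slope * py),
    history_pneumonia = stats::runif(n) < p$p_pneumonia,
    asbestos = FALSE,
    smoking_status = ifelse(current, "current", "former"),
    smoking_duration = duration,
    smoking_intensity = intensity,
    years_since_quit = quit,
    pack_years = py,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Draws `scenario$n` complete subjects; for the NLST-like scenario,
#' rejection sampling enforces the eligibility constraint (at least 30
#' pack-years; former smokers quit under 15 years ago) so 100% of subjects
#' pass [nlst_eligible()]. Reproducible under `seed`.
#'
#' @param scenario from [cohort_scenario()].
#' @param seed RNG seed.
#' @return complete cohort data.frame in the [cohort_schema()] layout.
#' @export
generate_cohort <- function(scenario, seed = 1) {
  n <- scenario$n
  stopifnot(n >= 1)
  with_seed(seed, {
    if (!scenario$eligibility_constrained) {
      out <- draw_subjects(scenario, n)
    } else {
      out <- NULL
      drawn <- 0
      while (is.null(out) || nrow(out) < n) {
        batch <- draw_subjects(scenario, max(n, 1000))
        drawn <- drawn + nrow(batch)
        keep <- batch[which(nlst_eligible(batch)), , drop = FALSE]
        out <- rbind(out, keep)
        if (drawn >= 100 * n && nrow(out) < 0.01 * drawn)
          stop("configuration error: eligibility acceptance rate below 1%",
               call. = FALSE)
      }
      out <- out[seq_len(n), , drop = FALSE]
    }
    out$id <- sprintf("%s_%06d", scenario$name, seq_len(n))
    rownames(out) <- NULL
    out[, cohort_schema()$column]
  })
}

#' Simulate binary outcomes from a generating risk model
#'
#' Per-subject risk from the generating model, distorted on the logit scale
#' as `p' = plogis(a + b * qlogis(p))`, then a Bernoulli draw for incidence.
#' Lung-cancer death is a Bernoulli sub-event of incidence with the given
#' within-horizon case fatality, so death implies incidence.
#'
#' @param subjects complete cohort data.frame.
#' @param generating_model model id (default `"plcom2012"`).
#' @param horizon years (default 6).
#' @param distortion numeric `c(a, b)`: logit shift and scale; `c(0, 1)`
#'   leaves the generating risks undistorted.
#' @param case_fatality probability a simulated case dies within the horizon
#'   (default 0.5, reflecting the roughly half-of-cases death counts of the
#'   trial populations).
#' @param seed RNG seed.
#' @return data.frame `id`, `lc_incidence`, `lc_death`, `horizon`, plus the
#'   (distorted) generating probability as `true_risk`.
#' @export
simulate_outcomes <- function(subjects, generating_model = "plcom2012",
                              horizon = 6, distortion = c(0, 1),
                              case_fatality = 0.5, seed = 1) {
  pred <- predict_risk(subjects, generating_model, horizon)
  p <- stats::plogis(distortion[1] + distortion[2] * stats::qlogis(pred$probability))
  with_seed(seed, {
    inc <- stats::runif(nrow(subjects)) < p
    death <- inc & (stats::runif(nrow(subjects)) < case_fatality)
    data.frame(id = subjects$id, lc_incidence = inc, lc_death = death,
               horizon = horizon, true_risk = p, stringsAsFactors = FALSE)
  })
}

#' Per-field missingness rates emulating the trial questionnaires
#'
#' The `trial_like` profile carries the participant-weighted per-field
#' missingness rates of the four trial arms, together with a subject-level
#' clustering parameter `rho`: questionnaire non-response concentrates in
#' the same individuals, which is what makes the complete-case fraction
#' (about 0.93) higher than independent per-field blanking would give.
#'
#' @param name profile name (only `"trial_like"`).
#' @return list with `rates` (named per-field rates) and `rho`.
#' @export
missingness_profile <- function(name = "trial_like") {
  stopifnot(name == "trial_like")
  list(rates = c(race = 0.0082, education = 0.0107, bmi = 0.0121,
                 emphysema = 0.0064, personal_history_cancer = 0.0016,
                 family_history_lc = 0.0300, history_pneumonia = 0.0020,
                 smoking_duration = 0.0125, smoking_intensity = 0.0014,
                 years_since_quit = 0.0127),
       rho = 0.70)
}

#' Inject missing cells into a complete cohort
#'
#' Blanks cells per field at the given marginal rates. Under MCAR the
#' subject-level clustering factor is a standard-normal draw; under MAR it is
#' the rank-normal score of a named observed predictor, so missingness
#' depends on that predictor while the marginal per-field rates are
#' preserved (Gaussian-copula construction). `years_since_quit` is only
#' blanked for former smokers (it is structural for current smokers);
#' `pack_years` is blanked whenever duration or intensity is.
#'
#' @param subjects complete cohort data.frame.
#' @param rates named per-field missingness rates in \[0, 1).
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param mar_predictor field driving MAR missingness (must itself have no
#'   missingness rate).
#' @param rho subject-level clustering loading in \[0, 1).
#' @param seed RNG seed.
#' @return cohort data.frame with `NA` cells injected.
#' @export
inject_missingness <- function(subjects, rates, mechanism = c("MCAR", "MAR"),
                               mar_predictor = NULL, rho = 0, seed = 1) {
  mechanism <- match.arg(mechanism)
  stopifnot(all(rates >= 0 & rates < 1), rho >= 0, rho < 1)
  if (mechanism == "MAR") {
    if (is.null(mar_predictor))
      stop("MAR requires mar_predictor", call. = FALSE)
    if (!is.null(rates[mar_predictor]) && !is.na(rates[mar_predictor]) &&
        rates[mar_predictor] > 0)
      stop("configuration error: MAR predictor cannot itself be missing",
           call. = FALSE)
    if (rho == 0) rho <- 0.5
  }
  n <- nrow(subjects)
  with_seed(seed, {
    z <- if (mechanism == "MCAR") stats::rnorm(n)
         else stats::qnorm(rank(subjects[[mar_predictor]],
                                ties.method = "random") / (n + 1))
    for (field in names(rates)) {
      r <- rates[[field]]
      if (r == 0 || !field %in% names(subjects)) next
      u <- stats::pnorm(rho * z + sqrt(1 - rho^2) * stats::rnorm(n))
      hit <- u < r
      if (field == "years_since_quit")
        hit <- hit & subjects$smoking_status == "former"
      if (field %in% c("smoking_duration", "smoking_intensity"))
        subjects$pack_years[hit] <- NA
      subjects[[field]][hit] <- NA
    }
    subjects
  })
}

#' Fraction of subjects with complete information
#'
#' @param subjects cohort data.frame.
#' @param fields fields counted towards completeness (default: every field
#'   subject to missingness in the trial-like profile).
#' @return proportion of rows complete on `fields`.
#' @export
complete_case_fraction <- function(subjects,
                                   fields = names(missingness_profile()$rates)) {
  fields <- intersect(fields, names(subjects))
  mean(stats::complete.cases(subjects[, fields, drop = FALSE]))
}
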