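# Fixture builders used across the suite.

# one complete subject row; override any field by name
make_subject <- function(...) {
  base <- data.frame(
    id = "s1", age = 62, gender = "male", race = "white", education = 4,
    bmi = 27, copd = FALSE, emphysema = FALSE,
    personal_history_cancer = FALSE, family_history_lc = FALSE,
    history_pneumonia = FALSE, asbestos = FALSE,
    smoking_status = "current", smoking_duration = 40,
    smoking_intensity = 20, years_since_quit = 0, pack_years = 40,
    stringsAsFactors = FALSE)
  over <- list(...)
  base[names(over)] <- over
  base
}

make_cohort <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, rows)
  out$id <- sprintf("s%d", seq_len(nrow(out)))
  out
}

# the five risk-factor profiles used as worked examples (ever-smokers with
# heterogeneous covariates); quit-years 0 for current smokers
example_profiles <- function() {
  make_cohort(
    make_subject(age = 70, gender = "male", race = "white", education = 2,
                 smoking_status = "current", smoking_intensity = 30,
                 smoking_duration = 55, years_since_quit = 0, bmi = 28,
                 copd = TRUE, family_history_lc = TRUE,
                 pack_years = 55 * 30 / 20),
    make_subject(age = 63, gender = "female", race = "black", education = 5,
                 smoking_status = "former", smoking_intensity = 15,
                 smoking_duration = 40, years_since_quit = 10, bmi = 25,
                 history_pneumonia = TRUE, pack_years = 40 * 15 / 20),
    make_subject(age = 65, gender = "male", race = "asian", education = 4,
                 smoking_status = "former", smoking_intensity = 10,
                 smoking_duration = 30, years_since_quit = 14, bmi = 24,
                 asbestos = TRUE, pack_years = 30 * 10 / 20),
    make_subject(age = 58, gender = "female", race = "hispanic", education = 6,
                 smoking_status = "current", smoking_intensity = 5,
                 smoking_duration = 38, years_since_quit = 0, bmi = 22,
                 personal_history_cancer = TRUE, pack_years = 38 * 5 / 20),
    make_subject(age = 50, gender = "female", race = "white", education = 5,
                 smoking_status = "current", smoking_intensity = 5,
                 smoking_duration = 30, years_since_quit = 0, bmi = 22,
                 pack_years = 30 * 5 / 20))
}

# random valid ever-smoker profiles for property sweeps
random_profiles <- function(n, seed = 1) {
  set.seed(seed)
  current <- runif(n) < 0.5
  age <- sample(50:78, n, replace = TRUE)
  start <- sample(12:25, n, replace = TRUE)
  quit <- ifelse(current, 0, sample(1:20, n, replace = TRUE))
  duration <- pmax(age - start - quit, 2)
  out <- do.call(rbind, replicate(n, make_subject(), simplify = FALSE))
  out$id <- sprintf("r%d", seq_len(n))
  out$age <- age
  out$gender <- sample(c("male", "female"), n, replace = TRUE)
  out$race <- sample(c("white", "black", "asian"), n, replace = TRUE)
  out$education <- sample(1:6, n, replace = TRUE)
  out$bmi <- round(runif(n, 19, 38), 1)
  out$copd <- runif(n) < 0.15
  out$emphysema <- runif(n) < 0.07
  out$personal_history_cancer <- runif(n) < 0.05
  out$family_history_lc <- runif(n) < 0.15
  out$history_pneumonia <- runif(n) < 0.2
  out$smoking_status <- ifelse(current, "current", "former")
  out$smoking_duration <- duration
  out$smoking_intensity <- sample(3:60, n, replace = TRUE)
  out$years_since_quit <- quit
  out$pack_years <- pack_years(out$smoking_duration, out$smoking_intensity)
  out
}

# toy annual-cycle payload with constant per-cycle probabilities
toy_cycle_payload <- function(p_lc, p_death = NULL) {
  cloglog <- function(p) if (p == 0) -Inf else log(-log(1 - p))
  cfg <- list(model_id = "bach", outcome = "incidence", horizon = 1,
              type = "annual_cycle",
              covariates = c("age", "smoking_status", "smoking_duration",
                             "smoking_intensity", "years_since_quit"),
              competing_mortality = !is.null(p_death),
              lc_hazard = list(intercept = cloglog(p_lc)))
  if (!is.null(p_death))
    cfg$death_hazard <- list(intercept = cloglog(p_death))
  cfg
}
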