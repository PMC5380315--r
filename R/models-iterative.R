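# Annual-cycle models (Bach, Knoke): 1-y hazards composed over the horizon.
#
# Within each one-year cycle the age advances by one year, smoking duration
# advances for current smokers, and years-since-quit advances for former
# smokers (integer-year steps; fractional ages are truncated to completed
# years). The Bach composition couples the annual lung-cancer probability
# with an annual competing-death probability:
#
#   risk = sum_{k=0}^{horizon-1} S_lc(k) * S_death(k) * p_lc(k)
#
# where S_.(k) are products of prior cycles' complements. The Knoke death
# model composes without a competing-death term: risk = 1 - prod(1 - p_k).
#
# Annual hazard blocks use a complementary-log-log link,
# p = 1 - exp(-exp(lp)), so that the linear predictor is a log cumulative
# hazard; lp = -Inf yields an exactly-zero hazard (used by zero-hazard test
# payloads).

annual_prob <- function(block, age, duration, intensity, quit, current) {
  lp <- rep(block$intercept, length(age))
  add <- function(lp, term, x) if (is.null(term)) lp else lp + term * x
  lp <- add(lp, block$age, age - (block$age_center %||% 0))
  lp <- add(lp, block$duration, duration)
  lp <- add(lp, block$log_intensity, log1p(intensity))
  lp <- add(lp, block$quit_years, quit)
  if (!is.null(block$current)) lp <- lp + block$current * as.numeric(current)
  1 - exp(-exp(lp))
}

annual_cycle_risk <- function(subjects, cfg, horizon) {
  n <- nrow(subjects)
  age <- floor(subjects$age)
  duration <- subjects$smoking_duration
  quit <- subjects$years_since_quit
  intensity <- subjects$smoking_intensity
  current <- subjects$smoking_status == "current"

  s_lc <- rep(1, n)      # survival free of the target event
  s_death <- rep(1, n)   # survival free of competing death
  risk <- rep(0, n)
  for (k in seq_len(horizon) - 1L) {
    p_lc <- annual_prob(cfg$lc_hazard, age + k, duration, intensity, quit,
                        current)
    risk <- risk + s_lc * s_death * p_lc
    s_lc <- s_lc * (1 - p_lc)
    if (isTRUE(cfg$competing_mortality)) {
      p_d <- annual_prob(cfg$death_hazard, age + k, duration, intensity, quit,
                         current)
      s_death <- s_death * (1 - p_d)
    }
    duration <- duration + as.numeric(current)
    quit <- quit + as.numeric(!current)
  }
  risk
}
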