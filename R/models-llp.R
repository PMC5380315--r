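# Liverpool Lung Project (LLP) family: age-sex baseline absolute risk
# combined with covariate odds ratios.
#
# The LLP combination rule converts the age-sex stratum's 5-y baseline
# absolute risk to odds, multiplies in the subject's covariate odds ratios
# (smoking-duration category, personal history of cancer, family history of
# lung cancer by onset age, history of pneumonia, asbestos exposure) and
# converts back to an absolute 5-y risk. Family-history onset age defaults to
# "late" (> 60 y) because trial questionnaires record occurrence only, and
# most lung cancers in relatives are diagnosed after 60; asbestos defaults to
# FALSE when the field is entirely missing.

llp_age_band <- function(age, bands) {
  lower <- vapply(bands, function(b) b$min, numeric(1))
  idx <- findInterval(age, lower)
  if (any(idx == 0))
    stop("domain error: age below the youngest LLP baseline band", call. = FALSE)
  idx
}

llp_duration_or <- function(duration, table) {
  lower <- vapply(table, function(b) b$min, numeric(1))
  or <- vapply(table, function(b) b$or, numeric(1))
  or[findInterval(duration, lower)]
}

llp_risk <- function(subjects, cfg) {
  bands <- cfg$baseline_risk$bands
  idx <- llp_age_band(subjects$age, bands)
  base <- ifelse(subjects$gender == "male",
                 vapply(bands, function(b) b$male, numeric(1))[idx],
                 vapply(bands, function(b) b$female, numeric(1))[idx])
  odds <- base / (1 - base)
  odds <- odds * llp_duration_or(subjects$smoking_duration,
                                 cfg$odds_ratios$smoking_duration)
  ors <- cfg$odds_ratios
  mult_flag <- function(odds, flag, or) {
    if (is.null(or)) return(odds)
    odds * ifelse(flag, or, 1)
  }
  odds <- mult_flag(odds, subjects$personal_history_cancer,
                    ors$personal_history_cancer)
  # onset-age split: occurrence-only questionnaires are mapped to "late"
  fh_or <- ors$family_history_late %||% 1
  odds <- mult_flag(odds, subjects$family_history_lc, fh_or)
  odds <- mult_flag(odds, subjects$history_pneumonia, ors$history_pneumonia)
  asb <- subjects$asbestos
  asb[is.na(asb)] <- FALSE
  odds <- mult_flag(odds, asb, ors$asbestos)
  odds / (1 + odds)
}
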