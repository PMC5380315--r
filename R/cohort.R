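# Cohort data model: schema, CSV I/O, implausible-value recoding, derived
# smoking quantities and pack-year-based screening eligibility.
#
# A cohort is a plain data.frame with one row per subject. Empty CSV cells
# denote missing values (NA). All fields except `id` and `age` may be missing.

RACE_LEVELS <- c("white", "black", "hispanic", "asian",
                 "pacific_islander", "native_american")
GENDER_LEVELS <- c("male", "female")
SMOKING_LEVELS <- c("current", "former", "never")

COHORT_NUMERIC <- c("age", "education", "bmi", "smoking_duration",
                    "smoking_intensity", "years_since_quit", "pack_years")
COHORT_LOGICAL <- c("copd", "emphysema", "personal_history_cancer",
                    "family_history_lc", "history_pneumonia", "asbestos")
COHORT_CHARACTER <- c("id", "gender", "race", "smoking_status")

#' Column dictionary of the cohort CSV schema
#'
#' @return data.frame with columns `column`, `type`, `levels` describing the
#'   person-level cohort table: demographic fields, comorbidity flags, the
#'   smoking history block (status, duration in years, intensity in
#'   cigarettes/day, years since quitting, pack-years) and the opaque `id`.
#' @export
cohort_schema <- function() {
  cols <- c(COHORT_CHARACTER, COHORT_NUMERIC, COHORT_LOGICAL)
  type <- c(rep("character", length(COHORT_CHARACTER)),
            rep("numeric", length(COHORT_NUMERIC)),
            rep("logical", length(COHORT_LOGICAL)))
  lev <- rep("", length(cols))
  lev[cols == "gender"] <- paste(GENDER_LEVELS, collapse = "|")
  lev[cols == "race"] <- paste(RACE_LEVELS, collapse = "|")
  lev[cols == "smoking_status"] <- paste(SMOKING_LEVELS, collapse = "|")
  data.frame(column = cols, type = type, levels = lev,
             stringsAsFactors = FALSE)
}

OUTCOME_COLUMNS <- c("id", "lc_incidence", "lc_death", "horizon")

coerce_numeric_col <- function(x, col, issues) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  for (i in bad) {
    issues$add(i, col, x[i], "non-numeric value")
  }
  out[x == "" | is.na(x)] <- NA_real_
  out
}

issue_collector <- function() {
  rows <- list()
  list(
    add = function(row, column, value, problem) {
      rows[[length(rows) + 1]] <<- data.frame(
        row = row, column = column, value = as.character(value),
        problem = problem, stringsAsFactors = FALSE)
    },
    get = function() {
      if (length(rows) == 0)
        data.frame(row = integer(), column = character(), value = character(),
                   problem = character(), stringsAsFactors = FALSE)
      else do.call(rbind, rows)
    })
}

#' Read a person-level cohort CSV
#'
#' Parses a comma-separated, UTF-8, headered cohort file following
#' [cohort_schema()]. Empty cells denote missing values. Rows that cannot be
#' parsed are reported in the `issues` table (with row index), never silently
#' dropped. Outcome columns (`lc_incidence`, `lc_death`, `horizon`), if
#' present, are split into a separate outcomes table.
#'
#' @param path path to a CSV file.
#' @return list with elements `subjects` (data.frame), `outcomes` (data.frame
#'   or `NULL`) and `issues` (data.frame of row-level parse problems).
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, check.names = FALSE)
  mandatory <- c("id", "age")
  absent <- setdiff(mandatory, names(raw))
  if (length(absent) > 0)
    stop(sprintf("cohort schema error: missing mandatory column(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)

  issues <- issue_collector()
  n <- nrow(raw)
  subj <- data.frame(id = raw$id, stringsAsFactors = FALSE)

  for (col in COHORT_NUMERIC) {
    subj[[col]] <- if (col %in% names(raw))
      coerce_numeric_col(raw[[col]], col, issues) else NA_real_
  }
  for (col in COHORT_LOGICAL) {
    if (col %in% names(raw)) {
      x <- toupper(trimws(raw[[col]]))
      out <- rep(NA, n)
      out[x %in% c("TRUE", "T", "1", "YES")] <- TRUE
      out[x %in% c("FALSE", "F", "0", "NO")] <- FALSE
      bad <- which(x != "" & is.na(out))
      for (i in bad) issues$add(i, col, raw[[col]][i], "non-logical value")
      subj[[col]] <- out
    } else subj[[col]] <- NA
  }
  for (col in c("gender", "race", "smoking_status")) {
    levels_ok <- switch(col, gender = GENDER_LEVELS, race = RACE_LEVELS,
                        smoking_status = SMOKING_LEVELS)
    if (col %in% names(raw)) {
      x <- tolower(trimws(raw[[col]]))
      x[x == ""] <- NA_character_
      bad <- which(!is.na(x) & !(x %in% levels_ok))
      for (i in bad) issues$add(i, col, raw[[col]][i], "unknown level")
      x[!is.na(x) & !(x %in% levels_ok)] <- NA_character_
      subj[[col]] <- x
    } else subj[[col]] <- NA_character_
  }

  if (any(!is.na(subj$smoking_status) & subj$smoking_status == "never"))
    warning("cohort contains never-smokers; risk models exclude them ",
            "(they are parsed but should be filtered before prediction)")

  outcomes <- NULL
  if (all(c("lc_incidence", "lc_death") %in% names(raw))) {
    parse_bool <- function(x) {
      x <- toupper(trimws(x))
      out <- rep(NA, length(x))
      out[x %in% c("TRUE", "T", "1", "YES")] <- TRUE
      out[x %in% c("FALSE", "F", "0", "NO")] <- FALSE
      out
    }
    outcomes <- data.frame(
      id = raw$id,
      lc_incidence = parse_bool(raw$lc_incidence),
      lc_death = parse_bool(raw$lc_death),
      horizon = if ("horizon" %in% names(raw))
        suppressWarnings(as.numeric(raw$horizon)) else 6,
      stringsAsFactors = FALSE)
  }

  subj <- subj[, cohort_schema()$column]
  list(subjects = subj, outcomes = outcomes, issues = issues$get())
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: missing values become empty cells; round-trips
#' the typed representation including missingness.
#'
#' @param subjects cohort data.frame.
#' @param path output path.
#' @param outcomes optional outcomes data.frame to merge in by `id`.
#' @export
write_cohort <- function(subjects, path, outcomes = NULL) {
  out <- subjects
  if (!is.null(outcomes)) {
    out <- merge(out, outcomes, by = "id", all.x = TRUE, sort = FALSE)
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Recode implausible values
#'
#' Applies the data-hygiene rules used when harmonizing the trial
#' questionnaires: smoking intensity above 100 cigarettes/day is capped at
#' 100; BMI below 14 kg/m2 is raised to 14 and above 60 kg/m2 lowered to 60.
#' Every change is recorded in a change log. Idempotent.
#'
#' @param subjects cohort data.frame.
#' @return list with `subjects` (recoded) and `log` (data.frame with columns
#'   `id`, `field`, `old`, `new`).
#' @export
recode_implausible <- function(subjects) {
  log_rows <- list()
  note <- function(idx, field, old, new) {
    if (length(idx) > 0)
      log_rows[[length(log_rows) + 1]] <<- data.frame(
        id = subjects$id[idx], field = field, old = old, new = new,
        stringsAsFactors = FALSE)
  }
  i <- which(!is.na(subjects$smoking_intensity) & subjects$smoking_intensity > 100)
  note(i, "smoking_intensity", subjects$smoking_intensity[i], 100)
  subjects$smoking_intensity[i] <- 100

  i <- which(!is.na(subjects$bmi) & subjects$bmi < 14)
  note(i, "bmi", subjects$bmi[i], 14)
  subjects$bmi[i] <- 14

  i <- which(!is.na(subjects$bmi) & subjects$bmi > 60)
  note(i, "bmi", subjects$bmi[i], 60)
  subjects$bmi[i] <- 60

  log <- if (length(log_rows) == 0)
    data.frame(id = character(), field = character(), old = numeric(),
               new = numeric(), stringsAsFactors = FALSE)
  else do.call(rbind, log_rows)
  list(subjects = subjects, log = log)
}

#' Pack-years of smoking
#'
#' Cumulative exposure: years smoked times cigarettes per day, divided by 20
#' (a pack). Missingness propagates.
#'
#' @param duration years smoked (>= 0).
#' @param intensity cigarettes per day (>= 0).
#' @return pack-years (numeric, vectorized).
#' @examples
#' pack_years(40, 20) # 40
#' @export
pack_years <- function(duration, intensity) {
  duration * intensity / 20
}

#' Fill derived pack-years and flag inconsistent reports
#'
#' Computes pack-years from duration and intensity where absent; where a
#' reported value coexists with both components, flags (does not alter)
#' values deviating from the product by more than `tolerance` (relative).
#'
#' @param subjects cohort data.frame.
#' @param tolerance relative tolerance for reported-vs-derived agreement.
#' @return list with `subjects` (pack_years filled where derivable) and
#'   `flags` (data.frame `id`, `reported`, `derived`).
#' @export
derive_pack_years <- function(subjects, tolerance = 0.10) {
  derived <- pack_years(subjects$smoking_duration, subjects$smoking_intensity)
  fill <- is.na(subjects$pack_years) & !is.na(derived)
  both <- !is.na(subjects$pack_years) & !is.na(derived) & derived > 0
  rel <- abs(subjects$pack_years - derived) / pmax(derived, 1e-12)
  flag_idx <- which(both & rel > tolerance)
  subjects$pack_years[fill] <- derived[fill]
  flags <- data.frame(id = subjects$id[flag_idx],
                      reported = subjects$pack_years[flag_idx],
                      derived = derived[flag_idx],
                      stringsAsFactors = FALSE)
  list(subjects = subjects, flags = flags)
}

#' Pack-year-based screening eligibility (NLST/USPSTF smoking criteria)
#'
#' A subject is eligible when a current or former smoker with at least 30
#' pack-years who, if quit, quit less than 15 years ago. An optional age
#' window (e.g. 55-74 as enrolled in the NLST, 55-80 per USPSTF) can be
#' applied; the default applies no age window, matching the criteria's use as
#' a comparator strategy within an already age-eligible cohort.
#'
#' Missing pack-years, status or quit-years yield `NA` (indeterminate), never
#' `FALSE`.
#'
#' @param subjects cohort data.frame.
#' @param min_pack_years pack-year cutoff (default 30, inclusive).
#' @param max_quit_years quit-year cutoff (default 15, exclusive).
#' @param age_min,age_max optional age window bounds (inclusive).
#' @return logical vector (with `NA` for indeterminate rows).
#' @export
nlst_eligible <- function(subjects, min_pack_years = 30, max_quit_years = 15,
                          age_min = NULL, age_max = NULL) {
  py <- subjects$pack_years
  derived <- pack_years(subjects$smoking_duration, subjects$smoking_intensity)
  py[is.na(py)] <- derived[is.na(py)]
  status <- subjects$smoking_status
  quit <- subjects$years_since_quit

  smoking_ok <- ifelse(is.na(status), NA,
                ifelse(status == "never", FALSE,
                ifelse(status == "current", TRUE,
                       ifelse(is.na(quit), NA, quit < max_quit_years))))
  py_ok <- py >= min_pack_years
  elig <- py_ok & smoking_ok
  if (!is.null(age_min)) elig <- elig & (subjects$age >= age_min)
  if (!is.null(age_max)) elig <- elig & (subjects$age <= age_max)
  # never-smokers are ineligible regardless of missing pack-years
  elig[!is.na(status) & status == "never"] <- FALSE
  elig
}

#' Validate cohort invariants
#'
#' Checks the typed-representation invariants: age within \[18, 110\], BMI
#' within \[14, 60\] (post-recoding), education in 1..6, smoking duration
#' less than age, quit-years consistency with smoking status, and intensity
#' at most 100.
#'
#' @param subjects cohort data.frame.
#' @return data.frame of violations (`id`, `field`, `problem`); zero rows when
#'   the cohort is valid.
#' @export
validate_cohort <- function(subjects) {
  bad <- list()
  note <- function(idx, field, problem) {
    if (length(idx) > 0)
      bad[[length(bad) + 1]] <<- data.frame(
        id = subjects$id[idx], field = field, problem = problem,
        stringsAsFactors = FALSE)
  }
  note(which(!is.na(subjects$age) & (subjects$age < 18 | subjects$age > 110)),
       "age", "outside [18, 110]")
  note(which(!is.na(subjects$bmi) & (subjects$bmi < 14 | subjects$bmi > 60)),
       "bmi", "outside [14, 60]")
  note(which(!is.na(subjects$education) &
             !(subjects$education %in% 1:6)), "education", "not in 1..6")
  note(which(!is.na(subjects$smoking_duration) & !is.na(subjects$age) &
             subjects$smoking_duration >= subjects$age),
       "smoking_duration", "not less than age")
  note(which(!is.na(subjects$smoking_intensity) &
             subjects$smoking_intensity > 100),
       "smoking_intensity", "exceeds 100 after recoding")
  note(which(!is.na(subjects$smoking_status) & !is.na(subjects$years_since_quit) &
             subjects$smoking_status == "current" & subjects$years_since_quit != 0),
       "years_since_quit", "nonzero for current smoker")
  note(which(!is.na(subjects$smoking_status) & !is.na(subjects$years_since_quit) &
             subjects$smoking_status == "former" & subjects$years_since_quit <= 0),
       "years_since_quit", "not positive for former smoker")
  if (length(bad) == 0)
    data.frame(id = character(), field = character(), problem = character(),
               stringsAsFactors = FALSE)
  else do.call(rbind, bad)
}
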