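# Multiple imputation by chained equations over the cohort schema, plus
# Rubin's-rules pooling.
#
# Conditional model families (declared defaults; the field's convention):
#   binary      -> Bayesian logistic regression draw (coefficients drawn from
#                  the asymptotic normal posterior)
#   continuous  -> normal linear regression with a Bayesian coefficient/sigma
#                  draw and predictive-mean-matching (5 donors) so imputed
#                  values respect bounded, skewed observed distributions
#   categorical -> multinomial logistic (nnet), drawn from fitted class
#                  probabilities
#
# Variables are swept in increasing-missingness order each iteration.
# Structural constraints are enforced after each draw: years_since_quit is
# imputed only for former smokers (structural zero for current smokers), and
# recoding bounds (BMI 14-60, intensity <= 100) are respected. Observed
# values are never modified.

IMPUTABLE_BINARY <- c("copd", "emphysema", "personal_history_cancer",
                      "family_history_lc", "history_pneumonia", "asbestos")
IMPUTABLE_CONTINUOUS <- c("bmi", "education", "smoking_duration",
                          "smoking_intensity", "years_since_quit")
IMPUTABLE_CATEGORICAL <- c("race", "gender", "smoking_status")

# numeric predictor matrix used by every conditional model
impute_design <- function(data, exclude) {
  X <- data.frame(
    age = data$age,
    male = as.numeric(data$gender == "male"),
    current = as.numeric(data$smoking_status == "current"),
    duration = data$smoking_duration,
    intensity = data$smoking_intensity,
    quit = data$years_since_quit,
    bmi = data$bmi,
    education = data$education,
    copd = as.numeric(data$copd),
    family_history = as.numeric(data$family_history_lc))
  drop <- switch(exclude,
    gender = "male", smoking_status = "current",
    smoking_duration = "duration", smoking_intensity = "intensity",
    years_since_quit = "quit", family_history_lc = "family_history",
    exclude)
  X[, setdiff(names(X), drop), drop = FALSE]
}

draw_coefs <- function(fit) {
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  ok <- is.finite(beta) & is.finite(diag(V))
  if (!all(ok) || max(abs(beta), na.rm = TRUE) > 25)
    return(list(beta = beta, proper = FALSE))  # separation: use MAP fit
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(beta = beta, proper = FALSE))
  list(beta = beta + drop(t(ch) %*% stats::rnorm(length(beta))), proper = TRUE)
}

impute_binary_draw <- function(y_obs, X_obs, X_mis) {
  if (length(unique(y_obs)) == 1)           # degenerate conditional
    return(rep(y_obs[1], nrow(X_mis)) == 1)
  df <- data.frame(y = y_obs, X_obs)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                     family = stats::binomial()))
  beta <- draw_coefs(fit)$beta
  beta[is.na(beta)] <- 0
  mm <- cbind(1, as.matrix(X_mis))
  p <- stats::plogis(drop(mm %*% beta))
  stats::runif(length(p)) < p
}

impute_pmm_draw <- function(y_obs, X_obs, X_mis, donors = 5) {
  df <- data.frame(y = y_obs, X_obs)
  fit <- suppressWarnings(stats::lm(y ~ ., data = df))
  beta_hat <- stats::coef(fit)
  beta_hat[is.na(beta_hat)] <- 0
  res <- stats::residuals(fit)
  df_res <- max(fit$df.residual, 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df_res)
  V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  beta <- beta_hat
  if (!is.null(V) && all(is.finite(V))) {
    V[is.na(V)] <- 0
    ch <- tryCatch(chol(V * sigma2 / max(stats::sigma(fit)^2, 1e-12)),
                   error = function(e) NULL)
    if (!is.null(ch))
      beta <- beta_hat + drop(t(ch) %*% stats::rnorm(length(beta_hat)))
  }
  mm_obs <- cbind(1, as.matrix(X_obs))
  mm_mis <- cbind(1, as.matrix(X_mis))
  pred_obs <- drop(mm_obs %*% beta_hat)
  pred_mis <- drop(mm_mis %*% beta)
  vapply(pred_mis, function(pm) {
    d <- abs(pred_obs - pm)
    pool <- order(d)[seq_len(min(donors, length(d)))]
    y_obs[pool[sample.int(length(pool), 1)]]
  }, numeric(1))
}

impute_categorical_draw <- function(y_obs, X_obs, X_mis) {
  lev <- sort(unique(y_obs))
  if (length(lev) == 1) return(rep(lev, nrow(X_mis)))
  df <- data.frame(y = factor(y_obs, levels = lev), X_obs)
  fit <- tryCatch(
    suppressMessages(nnet::multinom(y ~ ., data = df, trace = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {                        # fallback to marginal draw
    warning("multinomial fit failed; falling back to marginal draw")
    return(sample(y_obs, nrow(X_mis), replace = TRUE))
  }
  p <- stats::predict(fit, newdata = data.frame(X_mis), type = "probs")
  if (is.null(dim(p))) {
    # single missing row (>2 classes) or two-class fit collapse to a vector
    p <- if (length(lev) == 2) cbind(1 - p, p) else matrix(p, nrow = 1)
  }
  apply(p, 1, function(pr) sample(lev, 1, prob = pr))
}

enforce_structure <- function(data) {
  cur <- !is.na(data$smoking_status) & data$smoking_status == "current"
  data$years_since_quit[cur] <- 0
  frm <- !is.na(data$smoking_status) & data$smoking_status == "former"
  fix <- frm & !is.na(data$years_since_quit) & data$years_since_quit <= 0
  data$years_since_quit[fix] <- 0.5
  data$bmi <- pmin(pmax(data$bmi, 14), 60)
  data$smoking_intensity <- pmin(data$smoking_intensity, 100)
  data$education <- as.integer(pmin(pmax(round(data$education), 1), 6))
  data$smoking_duration <- pmin(data$smoking_duration, data$age - 1)
  data
}

impute_one_variable <- function(data, v, miss) {
  X <- impute_design(data, exclude = v)
  obs <- !miss
  if (v %in% IMPUTABLE_BINARY) {
    data[[v]][miss] <- impute_binary_draw(as.numeric(data[[v]][obs]),
                                          X[obs, , drop = FALSE],
                                          X[miss, , drop = FALSE])
  } else if (v %in% IMPUTABLE_CONTINUOUS) {
    data[[v]][miss] <- impute_pmm_draw(data[[v]][obs],
                                       X[obs, , drop = FALSE],
                                       X[miss, , drop = FALSE])
  } else {
    data[[v]][miss] <- impute_categorical_draw(data[[v]][obs],
                                               X[obs, , drop = FALSE],
                                               X[miss, , drop = FALSE])
  }
  data
}

#' Multiple imputation by chained equations
#'
#' Produces `m` completed copies of the cohort. Missing cells are initialized
#' by marginal draws from the observed values, then refined by `iterations`
#' sweeps of per-variable conditional models (in increasing-missingness
#' order). Observed cells are never modified; results are reproducible under
#' `seed`.
#'
#' `years_since_quit` is imputed conditionally on smoking status: it is only
#' ever drawn for former smokers, and the structural zero for current smokers
#' is enforced after every sweep.
#'
#' @param subjects cohort data.frame (may contain missing cells).
#' @param m number of imputations (>= 2; default 20).
#' @param iterations chained-equation sweeps per imputation (default 10).
#' @param seed RNG seed.
#' @return list of `m` completed cohort data.frames.
#' @export
impute_mice <- function(subjects, m = 20, iterations = 10, seed = 1) {
  stopifnot(m >= 2, iterations >= 1)
  vars <- c(IMPUTABLE_BINARY, IMPUTABLE_CONTINUOUS, IMPUTABLE_CATEGORICAL)
  vars <- intersect(vars, names(subjects))
  miss <- lapply(vars, function(v) is.na(subjects[[v]]))
  names(miss) <- vars
  n_miss <- vapply(miss, sum, integer(1))
  todo <- names(sort(n_miss[n_miss > 0]))
  for (v in todo) {
    if (all(miss[[v]]))
      stop(sprintf(
        "configuration error: variable '%s' has no observed values (use donor imputation)",
        v), call. = FALSE)
  }
  if (length(todo) == 0) return(replicate(m, subjects, simplify = FALSE))

  with_seed(seed, lapply(seq_len(m), function(imp) {
    data <- subjects
    for (v in todo) {                       # marginal initialization
      mi <- miss[[v]]
      if (v == "years_since_quit") {
        frm <- !is.na(data$smoking_status) & data$smoking_status == "former"
        pool <- data[[v]][!mi & frm]
        if (length(pool) == 0) pool <- data[[v]][!mi]
      } else {
        pool <- data[[v]][!mi]
      }
      data[[v]][mi] <- pool[sample.int(length(pool), sum(mi), replace = TRUE)]
    }
    data <- enforce_structure(data)
    for (it in seq_len(iterations)) {
      for (v in todo) {
        mi <- miss[[v]]
        if (v == "years_since_quit") {
          # draw only for former smokers; structural zero otherwise
          frm <- !is.na(data$smoking_status) & data$smoking_status == "former"
          mi_draw <- mi & frm
          data$years_since_quit[mi & !frm] <- 0
          if (any(mi_draw)) {
            X <- impute_design(data, exclude = v)
            obs <- !mi & frm
            if (sum(obs) > 2)
              data[[v]][mi_draw] <- impute_pmm_draw(
                data[[v]][obs], X[obs, , drop = FALSE],
                X[mi_draw, , drop = FALSE])
          }
        } else if (any(mi)) {
          data <- impute_one_variable(data, v, mi)
        }
        data <- enforce_structure(data)
      }
    }
    # observed cells must be untouched
    for (v in todo) data[[v]][!miss[[v]]] <- subjects[[v]][!miss[[v]]]
    # refresh the derived pack-years where its components were imputed
    if ("pack_years" %in% names(data)) {
      fill <- is.na(data$pack_years)
      data$pack_years[fill] <- pack_years(data$smoking_duration[fill],
                                          data$smoking_intensity[fill])
    }
    data
  }))
}

#' Cross-cohort donor imputation of a wholly missing variable
#'
#' When a variable is unmeasured in the target cohort but observed in a donor
#' cohort (history of pneumonia, measured in the NLST but not the PLCO, is
#' the motivating case), the donor and target are stacked, the variable's
#' conditional model is fitted on donor rows, and `m` draws are taken for the
#' target rows.
#'
#' @param target cohort data.frame with `variable` entirely missing.
#' @param donor cohort data.frame with `variable` observed.
#' @param variable binary variable name to transfer.
#' @param m number of imputations.
#' @param seed RNG seed.
#' @return list of `m` completed target cohorts.
#' @export
impute_with_donor <- function(target, donor, variable, m = 20, seed = 1) {
  if (nrow(donor) == 0)
    stop("empty donor cohort", call. = FALSE)
  if (!variable %in% names(donor) || all(is.na(donor[[variable]])))
    stop(sprintf("donor cohort has no observed values of '%s'", variable),
         call. = FALSE)
  shared <- names(impute_design(target, exclude = variable))
  missing_pred <- shared[vapply(shared, function(nm)
    anyNA(impute_design(donor, exclude = variable)[[nm]]) ||
    anyNA(impute_design(target, exclude = variable)[[nm]]), logical(1))]
  if (length(missing_pred) > 0)
    stop(sprintf(
      "schema mismatch: predictors with missing values across cohorts: %s",
      paste(missing_pred, collapse = ", ")), call. = FALSE)

  Xd <- impute_design(donor, exclude = variable)
  Xt <- impute_design(target, exclude = variable)
  y <- as.numeric(donor[[variable]])
  keep <- !is.na(y)

  with_seed(seed, lapply(seq_len(m), function(imp) {
    out <- target
    if (length(unique(y[keep])) == 1) {
      out[[variable]] <- y[keep][1] == 1
      return(out)
    }
    df <- data.frame(y = y[keep], Xd[keep, , drop = FALSE])
    fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                       family = stats::binomial()))
    dc <- draw_coefs(fit)
    mm <- cbind(1, as.matrix(Xt))
    p <- stats::plogis(drop(mm %*% dc$beta))
    out[[variable]] <- stats::runif(nrow(Xt)) < p
    out
  }))
}

#' Rubin's-rules pooling of a statistic across imputations
#'
#' Combines per-imputation point estimates and within-imputation variances:
#' pooled estimate `q_bar`, within-variance `u_bar`, between-variance `b`,
#' total variance `t_var = u_bar + (1 + 1/m) b`, small-sample degrees of
#' freedom and a t-based 95% interval.
#'
#' @param estimates numeric vector of m >= 2 per-imputation estimates.
#' @param variances numeric vector of m within-imputation variances (>= 0).
#' @param level confidence level (default 0.95).
#' @return object of class `pooled_estimate`: list with `q_bar`, `u_bar`,
#'   `b`, `t_var`, `df`, `ci`, `m`.
#' @examples
#' rubin_pool(c(0.6, 0.8), c(0.01, 0.01))
#' @export
rubin_pool <- function(estimates, variances, level = 0.95) {
  m <- length(estimates)
  if (m < 2)
    stop("Rubin pooling needs m >= 2 (between-imputation variance undefined)",
         call. = FALSE)
  stopifnot(length(variances) == m, all(variances >= 0))
  q_bar <- mean(estimates)
  u_bar <- mean(variances)
  b <- stats::var(estimates)
  t_var <- u_bar + (1 + 1 / m) * b
  df <- if (b == 0) Inf else (m - 1) * (1 + u_bar / ((1 + 1 / m) * b))^2
  alpha <- 1 - level
  half <- stats::qt(1 - alpha / 2, df) * sqrt(t_var)
  structure(list(q_bar = q_bar, u_bar = u_bar, b = b, t_var = t_var, df = df,
                 ci = c(lower = q_bar - half, upper = q_bar + half), m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled estimate (m = %d): %.4f  [%.4f, %.4f]\n",
              x$m, x$q_bar, x$ci["lower"], x$ci["upper"]))
  cat(sprintf("  within %.5f  between %.5f  total %.5f  df %.1f\n",
              x$u_bar, x$b, x$t_var, x$df))
  invisible(x)
}

#' Pool a statistic on a transformed scale
#'
#' AUCs and proportions are pooled on the logit scale (boundary-respecting
#' intervals); slopes and intercepts on the raw scale. Estimates and standard
#' errors are delta-method transformed, pooled with [rubin_pool()], and the
#' interval back-transformed.
#'
#' @param estimates per-imputation estimates on the raw scale.
#' @param ses per-imputation standard errors on the raw scale.
#' @param transform `"identity"` or `"logit"`.
#' @return list with `estimate`, `ci`, and the underlying `pooled_estimate`.
#' @export
pool_transformed <- function(estimates, ses, transform = c("identity", "logit")) {
  transform <- match.arg(transform)
  if (transform == "logit") {
    check_prob_open(estimates, "pooled estimates (logit scale)")
    tr <- stats::qlogis(estimates)
    tr_se <- ses / (estimates * (1 - estimates))
    pooled <- rubin_pool(tr, tr_se^2)
    list(estimate = stats::plogis(pooled$q_bar),
         ci = stats::plogis(pooled$ci), pooled = pooled)
  } else {
    pooled <- rubin_pool(estimates, ses^2)
    list(estimate = pooled$q_bar, ci = pooled$ci, pooled = pooled)
  }
}
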