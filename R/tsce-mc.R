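# Monte Carlo branching-process oracle for the TSCE solution.
#
# Simulates the two-stage process directly: initiation events arrive as an
# inhomogeneous Poisson process at rate nu(t) (piecewise constant), and each
# initiated clone evolves as a birth-death-transformation branching process
# with per-cell rates (alpha, beta, mu) that switch at exposure-segment
# boundaries. Each replicate records the time of the first malignant cell;
# the empirical tumour-free survival curve with binomial standard errors is
# returned. Used as the independent stochastic check on the analytic
# closed-form solution; not part of the prediction path.

# first transformation time of a clone founded by one cell at `t0`, simulated
# by a segment-aware Gillespie algorithm; returns Inf if the clone dies out
# or reaches `t_max` without transforming.
simulate_clone <- function(t0, t_max, seg, rates, cell_cap = 1e5) {
  t <- t0
  n_cells <- 1L
  j <- findInterval(t, seg$t_start)
  repeat {
    total <- n_cells * (rates$alpha[j] + rates$beta[j] + rates$mu[j])
    t_next <- if (total > 0) t + stats::rexp(1, total) else Inf
    if (t_next >= min(seg$t_end[j], t_max)) {
      if (seg$t_end[j] >= t_max || j == nrow(seg)) return(Inf)
      t <- seg$t_end[j]
      j <- j + 1L
      next
    }
    t <- t_next
    u <- stats::runif(1) * (rates$alpha[j] + rates$beta[j] + rates$mu[j])
    if (u < rates$mu[j]) return(t)
    if (u < rates$mu[j] + rates$beta[j]) {
      n_cells <- n_cells - 1L
      if (n_cells == 0L) return(Inf)
    } else {
      n_cells <- n_cells + 1L
      if (n_cells > cell_cap)
        stop("clone population exceeded cap; parameters too supercritical ",
             "for the Monte Carlo oracle", call. = FALSE)
    }
  }
}

#' Monte Carlo empirical survival for the TSCE model
#'
#' @inheritParams tsce_survival
#' @param n number of replicate tissue histories (>= 1).
#' @param t_grid ages at which to evaluate the empirical curve.
#' @param seed RNG seed; fixed seed gives a bit-identical curve.
#' @return data.frame with `t`, `survival` (empirical no-cancer-by-t,
#'   lag-shifted like the analytic solution), and binomial `se`.
#' @export
tsce_mc_survival <- function(params, schedule, n, t_grid, seed = 1) {
  stopifnot(n >= 1)
  lag <- params$lag %||% 0
  t_max <- max(t_grid) - lag
  first_mal <- with_seed(seed, {
    vapply(seq_len(n), function(rep) {
      if (t_max <= 0) return(Inf)
      seg <- schedule[schedule$t_start < t_max, , drop = FALSE]
      seg$t_end <- pmin(seg$t_end, t_max)
      rates <- tsce_rates_at_dose(params, seg$dose)
      best <- Inf
      for (j in seq_len(nrow(seg))) {
        len <- seg$t_end[j] - seg$t_start[j]
        k <- stats::rpois(1, rates$nu[j] * len)
        if (k == 0) next
        births <- sort(seg$t_start[j] + stats::runif(k) * len)
        for (b in births) {
          if (b >= best) break  # later clones cannot beat an earlier event
          tm <- simulate_clone(b, best, seg, rates)
          best <- min(best, tm)
        }
      }
      best
    }, numeric(1))
  })
  surv <- vapply(t_grid, function(t) mean(first_mal > t - lag), numeric(1))
  data.frame(t = t_grid, survival = surv,
             se = sqrt(surv * (1 - surv) / n))
}
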