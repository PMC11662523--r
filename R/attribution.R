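#' Daily forward attributable fraction for heat
#'
#' Forward scheme: the exposure on day `t` contributes an attributable
#' fraction `af_t = 1 - exp(-c_t)` to the deaths of days `t..t+L`, where
#' `c_t` is the overall cumulative (lag-summed) log relative risk of the
#' day's temperature versus the reference (the regional minimum mortality
#' temperature), extrapolated log-linearly beyond the observed range. The
#' heat restriction sets `af_t = 0` whenever the temperature does not
#' exceed the reference; tiny negative cumulative risks just above a
#' grid-searched reference (an artifact of the discrete minimum) are
#' truncated at zero so fractions stay in `[0, 1)`.
#'
#' @param temps daily temperatures of one unit in time order.
#' @param reduced a [reduce_to_overall()] result.
#' @param reference reference temperature (degrees C).
#' @return numeric vector of daily attributable fractions.
#' @export
daily_af <- function(temps, reduced, reference) {
  cum <- extrapolate_curve(reduced, temps, reference = reference)
  pmax(ifelse(temps > reference, 1 - exp(-cum), 0), 0)
}

#' Daily forward attributable number
#'
#' `an_t = af_t * mean(deaths over t..t+lag_max)`: the fraction is applied
#' to the average daily deaths across the forward lag window. Trailing days
#' whose window extends past the end of the series average over the
#' available days and are flagged.
#'
#' @param af daily attributable fractions (one unit, time order).
#' @param deaths aligned daily death counts.
#' @param lag_max forward window length in days.
#' @return data frame with `an` and logical `incomplete_window`.
#' @export
daily_an <- function(af, deaths, lag_max) {
  n <- length(af)
  if (length(deaths) != n) hm_value_error("af and deaths must align")
  m <- forward_mean(deaths, lag_max)
  data.frame(an = af * m,
             incomplete_window = seq_len(n) > n - lag_max)
}

# mean of x over t..min(t+L, n), vectorised via cumulative sums
forward_mean <- function(x, L) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  hi <- pmin(seq_len(n) + L, n)
  (cs[hi + 1] - cs[seq_len(n)]) / (hi - seq_len(n) + 1)
}

#' Attributable fraction/number series for a whole panel
#'
#' Runs [daily_af()] and [daily_an()] over every unit's in-season series.
#' Each unit-year seasonal block is treated as one contiguous series: lag
#' windows do not reach across the off-season break, and the trailing days
#' of every season average over the remaining in-season days (flagged
#' `incomplete_window`).
#'
#' @param panel a [heat_panel()] (deaths observed or counterfactual).
#' @param reduced a [reduce_to_overall()] result.
#' @param reference reference temperature (the minimum mortality
#'   temperature).
#' @return data frame `unit`, `date`, `tmean`, `deaths`, `af`, `an`,
#'   `incomplete_window` over the in-season records.
#' @export
attribute_panel <- function(panel, reduced, reference) {
  s <- as.data.frame(panel[panel$in_season, , drop = FALSE])
  if (nrow(s) == 0) hm_value_error("panel has no in-season records")
  block <- paste(s$unit, format(s$date, "%Y"))
  s$af <- daily_af(s$tmean, reduced, reference)
  s$an <- NA_real_
  s$incomplete_window <- NA
  for (idx in split(seq_len(nrow(s)), block)) {
    res <- daily_an(s$af[idx], s$deaths[idx], reduced$spec$lag_max)
    s$an[idx] <- res$an
    s$incomplete_window[idx] <- res$incomplete_window
  }
  s[c("unit", "date", "tmean", "deaths", "af", "an", "incomplete_window")]
}

#' Aggregate attributable deaths over a window
#'
#' Sums the daily attributable numbers over a date window (and optional
#' unit subset); the relative excess is the ratio to all deaths in the same
#' window, in percent.
#'
#' @param attribution result of [attribute_panel()].
#' @param window `NULL` (whole span) or length-2 date range (inclusive).
#' @param units `NULL` or subset of unit labels.
#' @return one-row data frame `an_total`, `deaths_total`, `af_total_pct`.
#' @export
aggregate_attribution <- function(attribution, window = NULL, units = NULL) {
  d <- attribution
  if (!is.null(units)) d <- d[d$unit %in% units, , drop = FALSE]
  if (!is.null(window)) {
    window <- as.Date(window)
    d <- d[d$date >= window[1] & d$date <= window[2], , drop = FALSE]
  }
  if (nrow(d) == 0) hm_value_error("empty aggregation window")
  data.frame(an_total = sum(d$an), deaths_total = sum(d$deaths),
             af_total_pct = 100 * sum(d$an) / sum(d$deaths))
}

#' Annual attributable impacts and their linear trend
#'
#' Aggregates the attribution series per calendar year and fits an ordinary
#' least squares line to the annual relative excess.
#'
#' @inheritParams aggregate_attribution
#' @return list with `annual` (year, an_total, deaths_total, af_total_pct)
#'   and `trend` (OLS intercept and slope of af_total_pct on year).
#' @export
annual_impacts <- function(attribution) {
  yr <- as.numeric(format(attribution$date, "%Y"))
  if (length(unique(yr)) < 2) hm_value_error("at least two years required")
  an <- tapply(attribution$an, yr, sum)
  de <- tapply(attribution$deaths, yr, sum)
  annual <- data.frame(year = as.numeric(names(an)),
                       an_total = as.numeric(an),
                       deaths_total = as.numeric(de),
                       af_total_pct = 100 * as.numeric(an) / as.numeric(de))
  co <- stats::coef(stats::lm(af_total_pct ~ year, data = annual))
  list(annual = annual,
       trend = c(intercept = unname(co[1]), slope = unname(co[2])))
}

# Draw coefficient vectors from N(eta, vcov). Non-positive-definite
# covariances are symmetrised and eigenvalue-clipped at zero (with warning).
mvn_draws <- function(n, eta, vcov) {
  p <- length(eta)
  V <- (vcov + t(vcov)) / 2
  ch <- tryCatch(chol(V), error = function(e) {
    warning("coefficient covariance not positive definite; eigenvalues clipped at zero")
    e <- eigen(V, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    t(e$vectors %*% (sqrt(ev) * t(e$vectors)))
  })
  matrix(stats::rnorm(n * p), n, p) %*% ch + matrix(eta, n, p, byrow = TRUE)
}

#' Monte Carlo empirical confidence intervals
#'
#' Samples coefficient vectors from the multivariate normal implied by the
#' reduced fit, recomputes the requested totals for every draw through the
#' supplied closure, and returns the empirical 2.5th and 97.5th
#' percentiles. Reusing one set of draws for all windows keeps annual
#' series and window totals coherent.
#'
#' @param reduced a [reduce_to_overall()] result.
#' @param statistic function taking a `reduced_fit` (with resampled
#'   coefficients) and returning a named numeric vector of totals.
#' @param n_sim number of draws (default 1000).
#' @param seed integer seed for reproducibility.
#' @return list with `point` (statistic at the fitted coefficients), `lo`,
#'   `hi` (2.5/97.5 empirical percentiles) and the `draws` matrix.
#' @export
monte_carlo_eci <- function(reduced, statistic, n_sim = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  point <- statistic(reduced)
  E <- mvn_draws(n_sim, reduced$eta, reduced$vcov)
  draws <- matrix(NA_real_, n_sim, length(point),
                  dimnames = list(NULL, names(point)))
  r <- reduced
  for (i in seq_len(n_sim)) {
    r$eta <- E[i, ]
    draws[i, ] <- statistic(r)
  }
  list(point = point,
       lo = apply(draws, 2, stats::quantile, 0.025, type = 7),
       hi = apply(draws, 2, stats::quantile, 0.975, type = 7),
       draws = draws)
}

#' Attribution totals with empirical confidence intervals
#'
#' Convenience wrapper combining [attribute_panel()],
#' [aggregate_attribution()] and [monte_carlo_eci()] for a set of windows.
#' The temperature basis and forward death-window means are precomputed
#' once, so the per-draw cost is a single matrix-vector product.
#'
#' @inheritParams attribute_panel
#' @param windows named list of `NULL`/date-range windows (see
#'   [aggregate_attribution()]).
#' @param n_sim,seed see [monte_carlo_eci()].
#' @return data frame with one row per window and per measure (`an`,
#'   `af_pct`): point estimate and empirical 95% bounds.
#' @export
attribute_with_eci <- function(panel, reduced, reference,
                               windows = list(overall = NULL),
                               n_sim = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- as.data.frame(panel[panel$in_season, , drop = FALSE])
  if (nrow(s) == 0) hm_value_error("panel has no in-season records")
  block <- paste(s$unit, format(s$date, "%Y"))
  m_fwd <- unsplit(lapply(split(s$deaths, block), forward_mean,
                          L = reduced$spec$lag_max), block)
  D <- sweep(var_basis(s$tmean, reduced$spec), 2,
             as.numeric(var_basis(reference, reduced$spec)))
  above <- s$tmean > reference
  win_idx <- lapply(windows, function(w) {
    if (is.null(w)) seq_len(nrow(s))
    else which(s$date >= as.Date(w)[1] & s$date <= as.Date(w)[2])
  })
  if (any(vapply(win_idx, length, 1L) == 0))
    hm_value_error("empty aggregation window")
  deaths_w <- vapply(win_idx, function(i) sum(s$deaths[i]), numeric(1))

  totals <- function(eta) {
    an <- pmax(ifelse(above, 1 - exp(-as.numeric(D %*% eta)), 0), 0) * m_fwd
    vapply(win_idx, function(i) sum(an[i]), numeric(1))
  }
  an_point <- totals(reduced$eta)
  E <- mvn_draws(n_sim, reduced$eta, reduced$vcov)
  an_draws <- apply(E, 1, totals)
  an_draws <- if (is.matrix(an_draws)) t(an_draws) else matrix(an_draws, ncol = 1)
  res <- data.frame(
    window = rep(names(windows), 2),
    measure = rep(c("an", "af_pct"), each = length(windows)),
    estimate = c(an_point, 100 * an_point / deaths_w),
    eci_lo = c(apply(an_draws, 2, stats::quantile, 0.025),
               apply(100 * t(t(an_draws) / deaths_w), 2, stats::quantile, 0.025)),
    eci_hi = c(apply(an_draws, 2, stats::quantile, 0.975),
               apply(100 * t(t(an_draws) / deaths_w), 2, stats::quantile, 0.975)),
    row.names = NULL)
  res
}
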