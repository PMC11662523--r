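# The cumulative (lag-summed) basis row for temperature T is
# b_var(T) (x) colSums(lag basis); with the temperature index fastest this
# expands each var column across the lag-sum weights.
cumulative_basis <- function(temps, spec) {
  Bv <- var_basis(temps, spec)
  lagsum <- colSums(lag_basis(spec))
  pv <- ncol(Bv)
  pl <- length(lagsum)
  Bv[, rep(seq_len(pv), pl), drop = FALSE] *
    matrix(rep(lagsum, each = pv), nrow(Bv), pv * pl, byrow = TRUE)
}

#' Cumulative exposure-response curve from a fitted cross-basis
#'
#' Predicts the overall cumulative (lag 0..L summed) log relative risk over
#' a temperature grid, centred at a reference temperature (usually the
#' minimum mortality temperature): `log RR(T) = [C(T) - C(ref)] beta` with
#' `C` the lag-summed cross-basis row. Standard errors come from the delta
#' quadratic form with the coefficient covariance; 95% confidence intervals
#' are Wald-type on the log scale. Grid temperatures beyond the boundary
#' knots are handled by the natural spline's linear tail (log-linear
#' extrapolation).
#'
#' @param fit a [fit_conditional_poisson()] result.
#' @param spec the [knot_spec()] the fit was built with (defaults to the one
#'   stored in the fit).
#' @param temp_grid temperatures (degrees C) at which to evaluate the curve.
#' @param reference reference temperature.
#' @return An `er_curve` data frame with columns `temp`, `log_rr`, `se`,
#'   `rr`, `rr_lo`, `rr_hi` and attribute `reference`.
#' @export
predict_cumulative <- function(fit, spec = fit$spec, temp_grid, reference) {
  if (length(temp_grid) == 0) hm_value_error("empty temperature grid")
  if (is.null(spec)) hm_value_error("a knot_spec is required")
  G <- cumulative_basis(temp_grid, spec)
  Gref <- cumulative_basis(reference, spec)
  D <- sweep(G, 2, as.numeric(Gref))
  log_rr <- as.numeric(D %*% fit$beta)
  se <- sqrt(pmax(rowSums((D %*% fit$vcov) * D), 0))
  out <- data.frame(temp = temp_grid, log_rr = log_rr, se = se,
                    rr = exp(log_rr),
                    rr_lo = exp(log_rr - 1.96 * se),
                    rr_hi = exp(log_rr + 1.96 * se))
  attr(out, "reference") <- reference
  class(out) <- c("er_curve", "data.frame")
  out
}

#' Reduce the cross-basis fit to the overall cumulative association
#'
#' Collapses the lag dimension: with the temperature index fastest, the
#' cumulative prediction is linear in `eta = M beta` where
#' `M[j, (m-1)*pv + j] = sum_l b_lag(l)[m]`. The reduced coefficients live
#' on the temperature basis alone and reproduce the full-fit cumulative
#' curve exactly; their covariance is `M V M'`.
#'
#' @inheritParams predict_cumulative
#' @return A `reduced_fit`: list with `eta`, `vcov` and the `spec`.
#' @export
reduce_to_overall <- function(fit, spec = fit$spec) {
  if (is.null(spec)) hm_value_error("a knot_spec is required")
  pv <- var_df(spec)
  lagsum <- colSums(lag_basis(spec))
  pl <- length(lagsum)
  M <- matrix(0, pv, pv * pl)
  for (m in seq_len(pl))
    M[cbind(seq_len(pv), (m - 1L) * pv + seq_len(pv))] <- lagsum[m]
  out <- list(eta = as.numeric(M %*% fit$beta),
              vcov = M %*% fit$vcov %*% t(M),
              spec = spec)
  class(out) <- "reduced_fit"
  out
}

#' Predict the cumulative curve from a reduced fit
#'
#' @param reduced a [reduce_to_overall()] result.
#' @param temps temperatures at which to predict (beyond-boundary values are
#'   extrapolated log-linearly).
#' @param reference reference temperature, or `NULL` for the uncentred
#'   linear predictor.
#' @return data frame with `temp`, `log_rr`, `se` (and `rr`, `rr_lo`,
#'   `rr_hi` when centred).
#' @export
predict_reduced <- function(reduced, temps, reference = NULL) {
  B <- var_basis(temps, reduced$spec)
  if (!is.null(reference))
    B <- sweep(B, 2, as.numeric(var_basis(reference, reduced$spec)))
  log_rr <- as.numeric(B %*% reduced$eta)
  se <- sqrt(pmax(rowSums((B %*% reduced$vcov) * B), 0))
  out <- data.frame(temp = temps, log_rr = log_rr, se = se)
  if (!is.null(reference)) {
    out$rr <- exp(log_rr)
    out$rr_lo <- exp(log_rr - 1.96 * se)
    out$rr_hi <- exp(log_rr + 1.96 * se)
    attr(out, "reference") <- reference
  }
  out
}

#' Extrapolate the cumulative curve beyond the observed range
#'
#' Evaluates the reduced-fit cumulative log relative risk at arbitrary
#' temperatures. Inside the boundary knots this is the fitted curve; beyond
#' them the natural cubic spline continues linearly, so the log relative
#' risk is extended log-linearly with the slope attained at the boundary —
#' the tail behaviour required when projecting onto warmer-than-observed
#' climates.
#'
#' @inheritParams predict_reduced
#' @return numeric vector of log relative risks.
#' @export
extrapolate_curve <- function(reduced, temps, reference = NULL) {
  predict_reduced(reduced, temps, reference)$log_rr
}

#' Locate the minimum mortality temperature
#'
#' Scans the cumulative curve on a fine grid (default 0.1 degrees C) over a
#' search window — by default the 1st-99th percentile of the in-season
#' temperatures, to keep noisy tails from driving the minimum — and returns
#' the grid temperature with the lowest cumulative log relative risk. Two
#' passes are used: the curve is first centred at a provisional reference
#' (the window midpoint), then re-centred at the provisional minimiser and
#' scanned once more. A minimiser on the window edge is returned with a
#' boundary flag (and warning), signalling that no interior minimum exists.
#'
#' @param reduced a [reduce_to_overall()] result.
#' @param window length-2 numeric search window, or `NULL` to derive it from
#'   `temps`.
#' @param temps in-season temperature observations used to derive the
#'   default window.
#' @param step grid spacing in degrees C (default 0.1).
#' @return list with `mmt` (degrees C) and `boundary` (logical).
#' @export
find_mmt <- function(reduced, window = NULL, temps = NULL, step = 0.1) {
  if (is.null(window)) {
    if (is.null(temps)) hm_value_error("either window or temps must be given")
    window <- unname(stats::quantile(temps, c(0.01, 0.99), type = 7))
  }
  if (window[1] >= window[2]) hm_value_error("degenerate search window")
  grid <- seq(window[1], window[2], by = step)
  centre <- stats::median(window)
  for (pass in 1:2) {
    lr <- predict_reduced(reduced, grid, reference = centre)$log_rr
    centre <- grid[which.min(lr)]
  }
  boundary <- centre <= grid[1] || centre >= grid[length(grid)]
  if (boundary)
    warning("minimum mortality temperature found on the search-window edge")
  list(mmt = centre, boundary = boundary)
}

#' Relative risk as a percent increase
#'
#' @param rr relative risk (> 0).
#' @return `(rr - 1) * 100`.
#' @examples percent_increase(5.13)
#' @export
percent_increase <- function(rr) {
  if (any(rr <= 0)) hm_value_error("relative risk must be positive")
  (rr - 1) * 100
}

#' Lag-specific relative risks at a given temperature
#'
#' The contribution of each single lag day to the overall association:
#' `log RR_l(T) = [b_var(T) - b_var(ref)] (x) b_lag(l) . beta`, with
#' delta-method 95% confidence intervals. The per-lag log relative risks sum
#' to the cumulative log relative risk.
#'
#' @inheritParams predict_cumulative
#' @param temp single exposure temperature.
#' @param reference reference temperature.
#' @return data frame with `lag`, `log_rr`, `se`, `rr`, `rr_lo`, `rr_hi`.
#' @export
lag_response <- function(fit, spec = fit$spec, temp, reference) {
  if (is.null(spec)) hm_value_error("a knot_spec is required")
  pv <- var_df(spec)
  Bl <- lag_basis(spec)
  dv <- as.numeric(var_basis(temp, spec)) - as.numeric(var_basis(reference, spec))
  rows <- t(vapply(seq_len(nrow(Bl)), function(i) {
    as.numeric(outer(dv, Bl[i, ]))      # var index fastest
  }, numeric(pv * ncol(Bl))))
  log_rr <- as.numeric(rows %*% fit$beta)
  se <- sqrt(pmax(rowSums((rows %*% fit$vcov) * rows), 0))
  data.frame(lag = 0:spec$lag_max, log_rr = log_rr, se = se,
             rr = exp(log_rr),
             rr_lo = exp(log_rr - 1.96 * se),
             rr_hi = exp(log_rr + 1.96 * se))
}
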