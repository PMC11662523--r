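#' Split a panel into temporal or seasonal subsets
#'
#' Temporal comparisons contrast two halves of the study period; seasonal
#' comparisons contrast early summer (May-June) against the season peak
#' (July-September). Years with anomalous mortality may be omitted before
#' splitting.
#'
#' @param panel a [heat_panel()].
#' @param mode `"interval"` (split at `interval_break`) or `"season_half"`
#'   (months 5-6 vs 7-9).
#' @param interval_break first calendar year of the second interval
#'   (default: midpoint of the observed years).
#' @param omit_years years removed from both subsets before splitting.
#' @return named list of two disjoint [heat_panel()] objects.
#' @export
split_panel <- function(panel, mode = c("interval", "season_half"),
                        interval_break = NULL, omit_years = NULL) {
  mode <- match.arg(mode)
  season <- attr(panel, "season")
  yr <- as.numeric(format(panel$date, "%Y"))
  if (!is.null(omit_years)) {
    panel <- panel[!(yr %in% omit_years), , drop = FALSE]
    yr <- yr[!(yr %in% omit_years)]
  }
  if (mode == "interval") {
    if (is.null(interval_break))
      interval_break <- floor((min(yr) + max(yr) + 1) / 2)
    a <- panel[yr < interval_break, , drop = FALSE]
    b <- panel[yr >= interval_break, , drop = FALSE]
    labels <- c(paste0(min(yr), "-", interval_break - 1),
                paste0(interval_break, "-", max(yr)))
  } else {
    mon <- as.numeric(format(panel$date, "%m"))
    a <- panel[mon %in% c(5, 6), , drop = FALSE]
    b <- panel[mon %in% c(7, 8, 9), , drop = FALSE]
    labels <- c("May-June", "July-September")
  }
  if (nrow(a) == 0 || nrow(b) == 0) hm_value_error("a split subset is empty")
  out <- list(heat_panel(as.data.frame(a), season = season),
              heat_panel(as.data.frame(b), season = season))
  names(out) <- labels
  out
}

#' Z-test for the difference of two log relative risks
#'
#' Two-sample comparison on the log relative risk scale:
#' `z = (log_rr_a - log_rr_b) / sqrt(se_a^2 + se_b^2)` with a two-sided
#' normal p-value — the interaction test for ratios compared across
#' independent subsets.
#'
#' @param log_rr_a,log_rr_b log relative risks of the two subsets.
#' @param se_a,se_b their standard errors (> 0).
#' @return data frame with `z` and `p`.
#' @examples z_test(0.2, 0.05, 0.1, 0.05)
#' @export
z_test <- function(log_rr_a, se_a, log_rr_b, se_b) {
  if (any(se_a <= 0) || any(se_b <= 0))
    hm_value_error("standard errors must be positive")
  z <- (log_rr_a - log_rr_b) / sqrt(se_a^2 + se_b^2)
  data.frame(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare heat risk between two panel subsets
#'
#' Fits the case time series model separately on two subsets using one
#' shared knot specification (derived from the pooled full-period
#' temperatures, so both fits use identical bases) and one shared reference
#' temperature (the regional minimum mortality temperature), then compares
#' the cumulative relative risks at the requested temperature percentiles
#' of the pooled in-season distribution with the Z-test.
#'
#' @param panel a [heat_panel()].
#' @param mode,interval_break,omit_years see [split_panel()].
#' @param percentiles temperature percentiles at which to compare (default
#'   50, 75, 95, 99).
#' @param reference shared reference temperature; default: the minimum
#'   mortality temperature estimated from the full panel.
#' @param spec shared [knot_spec()]; default derived from the pooled
#'   in-season temperatures.
#' @param scheme stratum scheme.
#' @return A `comparison_result` data frame: one row per percentile with
#'   both subsets' relative risks (95% CI), `z` and `p`.
#' @export
compare_heat_risk <- function(panel, mode = c("interval", "season_half"),
                              interval_break = NULL, omit_years = NULL,
                              percentiles = c(50, 75, 95, 99),
                              reference = NULL, spec = NULL,
                              scheme = "unit_year_month") {
  mode <- match.arg(mode)
  temps <- panel$tmean[panel$in_season]
  if (is.null(spec)) spec <- knot_spec(temps)
  if (is.null(reference)) {
    full <- fit_heat_model(panel, spec = spec, scheme = scheme)
    reference <- find_mmt(reduce_to_overall(full$fit), temps = temps)$mmt
  }
  halves <- split_panel(panel, mode, interval_break, omit_years)
  fits <- lapply(halves, function(p) fit_heat_model(p, spec = spec, scheme = scheme))
  tq <- unname(stats::quantile(temps, percentiles / 100, type = 7))
  curves <- lapply(fits, function(f)
    predict_cumulative(f$fit, spec, tq, reference = reference))
  a <- curves[[1]]; b <- curves[[2]]
  zt <- z_test(a$log_rr, a$se, b$log_rr, b$se)
  out <- data.frame(percentile = percentiles, temp = tq,
                    rr_a = a$rr, rr_a_lo = a$rr_lo, rr_a_hi = a$rr_hi,
                    rr_b = b$rr, rr_b_lo = b$rr_lo, rr_b_hi = b$rr_hi,
                    z = zt$z, p = zt$p)
  attr(out, "subsets") <- names(halves)
  attr(out, "reference") <- reference
  class(out) <- c("comparison_result", "data.frame")
  out
}
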