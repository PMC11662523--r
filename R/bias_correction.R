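#' Calibrate a climate member against observations (trend-preserving)
#'
#' Month-wise parametric calibration in the spirit of the ISIMIP
#' trend-preserving method: for every unit and calendar month the additive
#' offset is `C_m = mean(obs) - mean(model)` over the overlapping
#' historical years, and the residual scale is
#' `s_m = sd(obs residuals) / sd(model residuals)` with residuals taken
#' about each year's own monthly mean. Because the correction operates on
#' anomalies about the member's own running monthly mean, the member's
#' long-term change signal passes through the additive channel untouched.
#'
#' @param obs a [heat_panel()] with the observational temperatures.
#' @param model_hist a `climate_series` covering the historical period.
#' @param overlap_years optional explicit vector of calendar years to
#'   calibrate on; default is the intersection of both series' years
#'   (at least 10 years required).
#' @return `correction_params`: data frame `unit`, `month`, `offset`,
#'   `scale`.
#' @export
fit_correction <- function(obs, model_hist, overlap_years = NULL) {
  oy <- as.numeric(format(obs$date, "%Y"))
  my <- as.numeric(format(model_hist$date, "%Y"))
  if (is.null(overlap_years)) overlap_years <- intersect(unique(oy), unique(my))
  if (length(overlap_years) == 0)
    hm_value_error("no overlapping years between observations and model")
  if (length(overlap_years) < 10)
    hm_value_error("calibration overlap must span at least 10 years")
  o <- obs[oy %in% overlap_years, c("unit", "date", "tmean")]
  m <- model_hist[my %in% overlap_years, c("unit", "date", "tmean")]

  stat <- function(d) {
    mon <- format(d$date, "%m")
    ym <- paste(d$unit, format(d$date, "%Y"), mon)
    mu_ym <- stats::ave(d$tmean, ym)
    key <- paste(d$unit, mon)
    list(mean = tapply(d$tmean, key, mean),
         sd = tapply(d$tmean - mu_ym, key, stats::sd))
  }
  so <- stat(as.data.frame(o))
  sm <- stat(as.data.frame(m))
  keys <- sort(intersect(names(so$mean), names(sm$mean)))
  offset <- so$mean[keys] - sm$mean[keys]
  scale <- so$sd[keys] / sm$sd[keys]
  zero_var <- !is.finite(scale) | sm$sd[keys] == 0
  if (any(zero_var)) {
    warning("months with zero model variance: scale set to 1")
    scale[zero_var] <- 1
  }
  um <- do.call(rbind, strsplit(keys, " "))
  out <- data.frame(unit = um[, 1], month = um[, 2],
                    offset = as.numeric(offset), scale = as.numeric(scale),
                    stringsAsFactors = FALSE)
  class(out) <- c("correction_params", "data.frame")
  out
}

#' Apply a month-wise bias correction to a climate series
#'
#' Each daily value is re-expressed about its own unit-year-month mean
#' (`m_ym`): `corrected = m_ym + C_m + s_m * (value - m_ym)`. Applied
#' identically to historical and future segments, so the future-minus-
#' historical monthly-mean change of the member is preserved exactly.
#'
#' @param series a `climate_series`.
#' @param params a [fit_correction()] result covering every unit-month in
#'   the series.
#' @return the corrected `climate_series`.
#' @export
apply_correction <- function(series, params) {
  mon <- format(series$date, "%m")
  key <- paste(series$unit, mon)
  pkey <- paste(params$unit, params$month)
  hit <- match(key, pkey)
  if (anyNA(hit))
    hm_value_error("correction parameters missing for some unit-months")
  ym <- paste(series$unit, format(series$date, "%Y"), mon)
  m_ym <- stats::ave(series$tmean, ym)
  corrected <- m_ym + params$offset[hit] + params$scale[hit] * (series$tmean - m_ym)
  out <- series
  out$tmean <- corrected
  out
}
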