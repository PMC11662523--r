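#' Configuration for the synthetic panel generator
#'
#' Fixes a fully known ground truth for the exposure-lag-response surface
#' and the data-generating mechanism, so that every downstream stage (basis,
#' conditional fit, curves, attribution, projection) can be validated
#' against closed-form truth. Deaths are Poisson with log-mean
#' `log(baseline) + stratum effects + sum_l true_log_rr(x[t-l], l)`.
#'
#' The true surface is V-shaped on the log-risk scale: above `mmt_true`
#' the lag-0 log relative risk rises linearly with slope `slope_true` per
#' degree (so the relative risk grows exponentially), and below it rises
#' with the shallower `cold_slope_true` — the J shape typical of
#' temperature-mortality curves, with an identifiable interior minimum at
#' `mmt_true`. Lag effects decay geometrically (`lag_decay^lag`) over
#' `0..max_lag` days.
#'
#' Temperature is an annual sinusoid plus a per-unit offset, AR(1) noise and
#' a linear warming trend. Baseline mortality carries winter-peaking
#' seasonality, a secular trend and mean-one lognormal stratum
#' (unit-year-month) heterogeneity, so that unstratified fits are
#' confounded and the conditional likelihood is genuinely needed. Defaults
#' emulate a warm southern-European region: 47 units, 1980-2015, 0.3
#' deaths/unit/day, annual mean 16.6 degrees C with seasonal amplitude 8.2,
#' true minimum at 19 degrees C.
#'
#' @param n_units number of municipalities.
#' @param year_start,year_end calendar years covered (full years are
#'   generated; the seasonal window only flags records).
#' @param season month-day analysis window, default May 1 - Sep 30.
#' @param mmt_true true minimum mortality temperature (degrees C).
#' @param slope_true lag-0 log relative risk per degree above `mmt_true`
#'   (>= 0).
#' @param cold_slope_true lag-0 log relative risk per degree below
#'   `mmt_true`; default half of `slope_true`.
#' @param lag_decay geometric decay of lag effects, in (0, 1).
#' @param max_lag maximum lag (days, >= 0).
#' @param baseline_rate expected deaths/unit/day under the null surface
#'   (> 0).
#' @param unit_temp_offsets per-unit temperature offsets (degrees C);
#'   default evenly spaced on [-2, 2] (coastal-to-inland contrast).
#' @param ar1_rho,ar1_sd AR(1) autocorrelation and innovation standard
#'   deviation of the daily temperature noise.
#' @param warming_per_decade linear warming trend (degrees C per decade).
#' @param temp_mean,temp_amplitude,peak_doy annual-cycle parameters of the
#'   temperature sinusoid.
#' @param stratum_sd standard deviation (log scale) of the lognormal
#'   unit-year-month baseline factors (mean-one parameterisation).
#' @param baseline_seasonality amplitude (log scale) of winter-peaking
#'   baseline mortality seasonality.
#' @param baseline_trend_per_decade secular log-scale trend of baseline
#'   mortality per decade.
#' @param cause_thinning fraction of deaths removed at generation,
#'   emulating exclusion of cause-of-death chapters (0 = keep all).
#' @param seed integer seed; identical configurations generate identical
#'   panels.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_units = 47, year_start = 1980, year_end = 2015,
                         season = c("05-01", "09-30"),
                         mmt_true = 19, slope_true = 0.04,
                         cold_slope_true = slope_true / 2,
                         lag_decay = 0.6, max_lag = 10,
                         baseline_rate = 0.3,
                         unit_temp_offsets = NULL,
                         ar1_rho = 0.75, ar1_sd = 1.7,
                         warming_per_decade = 0.2,
                         temp_mean = 16.6, temp_amplitude = 8.2,
                         peak_doy = 206,
                         stratum_sd = 0.2,
                         baseline_seasonality = 0.15,
                         baseline_trend_per_decade = -0.05,
                         cause_thinning = 0,
                         seed = 1L) {
  if (lag_decay <= 0 || lag_decay >= 1) hm_config_error("lag_decay must be in (0, 1)")
  if (slope_true < 0) hm_config_error("slope_true must be >= 0")
  if (cold_slope_true < 0) hm_config_error("cold_slope_true must be >= 0")
  if (baseline_rate <= 0) hm_config_error("baseline_rate must be > 0")
  if (max_lag < 0) hm_config_error("max_lag must be >= 0")
  if (year_end < year_start) hm_config_error("year_end before year_start")
  if (cause_thinning < 0 || cause_thinning >= 1)
    hm_config_error("cause_thinning must be in [0, 1)")
  if (!is.null(season) && season[1] > season[2])
    hm_config_error("season window is empty")
  if (is.null(unit_temp_offsets)) {
    unit_temp_offsets <- if (n_units == 1) 0 else seq(-2, 2, length.out = n_units)
  }
  if (length(unit_temp_offsets) != n_units)
    hm_config_error("unit_temp_offsets must have one entry per unit")
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

#' True log relative risk surface of the generator
#'
#' Ground truth against which fitted curves and attribution are checked:
#' `slope_true * (temp - mmt_true) * lag_decay^lag` above the true minimum,
#' `cold_slope_true * (mmt_true - temp) * lag_decay^lag` below it, zero at
#' it.
#'
#' @param temp temperature (degrees C).
#' @param lag lag in days, within `0..max_lag`.
#' @param config a [synth_config()].
#' @return log relative risk contribution of lag `lag`.
#' @examples
#' cfg <- synth_config(slope_true = 0.05, cold_slope_true = 0, lag_decay = 0.5)
#' true_log_rr(21, 0, cfg)   # 0.05 * 2
#' true_log_rr(21, 3, cfg)   # 0.10 * 0.5^3
#' @export
true_log_rr <- function(temp, lag, config) {
  if (any(lag < 0 | lag > config$max_lag))
    hm_value_error("lag outside [0, max_lag]")
  dev <- ifelse(temp > config$mmt_true,
                config$slope_true * (temp - config$mmt_true),
                config$cold_slope_true * (config$mmt_true - temp))
  dev * config$lag_decay^lag
}

#' Cumulative true log relative risk of the generator
#'
#' The lag-summed ground-truth curve
#' `sum_{l=0..max_lag} true_log_rr(temp, l)`, centred at a reference
#' temperature — the benchmark for fitted cumulative exposure-response
#' curves and attribution.
#'
#' @inheritParams true_log_rr
#' @param reference reference temperature (default: the true minimum).
#' @return cumulative log relative risk versus the reference.
#' @export
true_cumulative_log_rr <- function(temp, config, reference = config$mmt_true) {
  gsum <- sum(config$lag_decay^(0:config$max_lag))
  at <- function(x) ifelse(x > config$mmt_true,
                           config$slope_true * (x - config$mmt_true),
                           config$cold_slope_true * (config$mmt_true - x)) * gsum
  at(temp) - at(reference)
}

# daily temperatures for one unit across contiguous dates
synth_unit_temps <- function(dates, offset, config) {
  n <- length(dates)
  doy <- as.numeric(format(dates, "%j"))
  years <- as.numeric(format(dates, "%Y"))
  seasonal <- config$temp_mean +
    config$temp_amplitude * cos(2 * pi * (doy - config$peak_doy) / 365.25)
  warming <- config$warming_per_decade * (years - config$year_start) / 10
  rho <- config$ar1_rho
  innov <- stats::rnorm(n, 0, config$ar1_sd)
  init <- stats::rnorm(1, 0, config$ar1_sd / sqrt(1 - rho^2))
  noise <- as.numeric(stats::filter(c(init, innov[-1]), rho, "recursive"))
  seasonal + offset + warming + noise
}

#' Generate a synthetic mortality-temperature panel
#'
#' Draws full-year daily temperature series per unit and Poisson death
#' counts under the configured exposure-lag-response surface (see
#' [synth_config()]). Within a year every seasonal day has a complete lag
#' history; only the first `max_lag` days of the first January lack one, and
#' their missing lag contributions are treated as null — they lie far
#' outside any seasonal window.
#'
#' @param config a [synth_config()].
#' @return A [heat_panel()] with the configured season attached and a
#'   `synth_config` attribute.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  dates <- seq(as.Date(paste0(config$year_start, "-01-01")),
               as.Date(paste0(config$year_end, "-12-31")), by = "day")
  nd <- length(dates)
  L <- config$max_lag
  gl <- config$lag_decay^(0:L)
  ym <- format(dates, "%Y-%m")
  years <- as.numeric(format(dates, "%Y"))
  doy <- as.numeric(format(dates, "%j"))
  log_season <- config$baseline_seasonality * cos(2 * pi * (doy - 15) / 365.25)
  log_trend <- config$baseline_trend_per_decade * (years - config$year_start) / 10

  units <- sprintf("unit_%02d", seq_len(config$n_units))
  out <- vector("list", config$n_units)
  for (i in seq_len(config$n_units)) {
    x <- synth_unit_temps(dates, config$unit_temp_offsets[i], config)
    dev <- ifelse(x > config$mmt_true,
                  config$slope_true * (x - config$mmt_true),
                  config$cold_slope_true * (config$mmt_true - x))
    # lag-summed exposure effect; missing history at the series start
    # contributes nothing
    effect <- numeric(nd)
    for (l in 0:L) {
      idx <- (l + 1):nd
      effect[idx] <- effect[idx] + dev[idx - l] * gl[l + 1]
    }
    # mean-one lognormal stratum factors per year-month
    umonths <- unique(ym)
    sf <- stats::rnorm(length(umonths), -config$stratum_sd^2 / 2, config$stratum_sd)
    log_mu <- log(config$baseline_rate) + log_season + log_trend +
      sf[match(ym, umonths)] + effect
    deaths <- stats::rpois(nd, exp(log_mu))
    if (config$cause_thinning > 0)
      deaths <- stats::rbinom(nd, deaths, 1 - config$cause_thinning)
    out[[i]] <- data.frame(unit = units[i], date = dates, tmean = x,
                           deaths = deaths, stringsAsFactors = FALSE)
  }
  panel <- heat_panel(do.call(rbind, out), season = config$season)
  attr(panel, "synth_config") <- config
  panel
}

#' Configuration for a synthetic climate-scenario member
#'
#' Describes one regional-climate-model / emission-pathway ensemble member
#' relative to an observational reference: an additive temperature bias, a
#' residual variance inflation and a linear warming trend.
#'
#' @param model_id,pathway_id non-empty labels (e.g. `"RCM1"`, `"rcp85"`).
#' @param bias_mean additive bias (degrees C).
#' @param bias_scale residual standard-deviation inflation factor (> 0).
#' @param warming_per_decade linear warming (degrees C per decade, from
#'   `year_start`).
#' @param year_start,year_end calendar years spanned by the member.
#' @param seed integer seed. Members generated from the same seed share
#'   their noise realisation, so two pathways differ only through the
#'   warming term.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(model_id, pathway_id, bias_mean = 0,
                            bias_scale = 1, warming_per_decade = 0.3,
                            year_start = 1981, year_end = 2100, seed = 1L) {
  if (!nzchar(model_id) || !nzchar(pathway_id))
    hm_config_error("model_id and pathway_id must be non-empty")
  if (bias_scale <= 0) hm_config_error("bias_scale must be > 0")
  if (year_end < year_start) hm_config_error("year_end before year_start")
  cfg <- as.list(environment())
  class(cfg) <- "scenario_config"
  cfg
}

#' Generate a synthetic climate-scenario series
#'
#' Builds daily scenario temperatures per unit as the reference day-of-year
#' climatology plus the configured additive bias, variance-inflated AR(1)
#' noise (autocorrelation and residual scale estimated from the reference
#' residuals) and the linear warming trend. The scenario must overlap the
#' reference years so that bias correction can be calibrated.
#'
#' @param config a [scenario_config()].
#' @param reference_panel a [heat_panel()] providing the observational
#'   climatology.
#' @return A `climate_series` data frame (`unit`, `date`, `tmean`) with
#'   `model_id` and `pathway_id` attributes.
#' @export
generate_scenario <- function(config, reference_panel) {
  stopifnot(inherits(config, "scenario_config"))
  if (nrow(reference_panel) == 0) hm_value_error("empty reference panel")
  ref_years <- as.numeric(format(reference_panel$date, "%Y"))
  if (config$year_start > max(ref_years) || config$year_end < min(ref_years))
    hm_config_error("scenario years do not overlap the reference years")
  set.seed(config$seed)

  md <- format(reference_panel$date, "%m-%d")
  clim_key <- paste(reference_panel$unit, md)
  clim <- tapply(reference_panel$tmean, clim_key, mean)

  # reference residual structure about the climatology
  resid <- reference_panel$tmean - clim[clim_key]
  sd_ref <- stats::sd(resid)
  rho <- stats::cor(resid[-1], resid[-length(resid)])  # lag-1, pooled

  dates <- seq(as.Date(paste0(config$year_start, "-01-01")),
               as.Date(paste0(config$year_end, "-12-31")), by = "day")
  nd <- length(dates)
  mds <- format(dates, "%m-%d")
  years <- as.numeric(format(dates, "%Y"))
  warming <- config$warming_per_decade * (years - config$year_start) / 10

  units <- sort(unique(reference_panel$unit))
  innov_sd <- sd_ref * sqrt(1 - rho^2)
  out <- vector("list", length(units))
  for (i in seq_along(units)) {
    base <- clim[paste(units[i], mds)]
    # Feb 29 absent from a non-leap reference climatology: borrow Feb 28
    miss <- is.na(base)
    if (any(miss)) base[miss] <- clim[paste(units[i], "02-28")]
    innov <- stats::rnorm(nd, 0, innov_sd)
    init <- stats::rnorm(1, 0, sd_ref)
    noise <- as.numeric(stats::filter(c(init, innov[-1]), rho, "recursive"))
    out[[i]] <- data.frame(unit = units[i], date = dates,
                           tmean = as.numeric(base) + config$bias_mean +
                             config$bias_scale * noise + warming,
                           stringsAsFactors = FALSE)
  }
  climate_series(do.call(rbind, out), config$model_id, config$pathway_id)
}

#' Construct or validate a climate series
#'
#' @param x data frame with columns `unit`, `date`, `tmean`.
#' @param model_id,pathway_id ensemble-member labels.
#' @return A `climate_series` data frame sorted by unit and date.
#' @export
climate_series <- function(x, model_id, pathway_id) {
  need <- c("unit", "date", "tmean")
  if (!all(need %in% names(x)))
    hm_format_error("climate series needs columns unit, date, tmean")
  x$unit <- as.character(x$unit)
  x$date <- as.Date(x$date)
  x <- x[order(x$unit, x$date), , drop = FALSE]
  rownames(x) <- NULL
  attr(x, "model_id") <- model_id
  attr(x, "pathway_id") <- pathway_id
  class(x) <- c("climate_series", "data.frame")
  x
}

#' Read/write climate-scenario series
#'
#' Delimited text with header `unit,date,tmean,model_id,pathway_id`.
#'
#' @param path file path.
#' @return [read_scenario()] returns a `climate_series`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) hm_format_error(paste("no such file:", path))
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit", "date", "tmean", "model_id", "pathway_id")
  if (!all(need %in% names(x)))
    hm_format_error("scenario file must have columns unit,date,tmean,model_id,pathway_id")
  climate_series(x[c("unit", "date", "tmean")], x$model_id[1], x$pathway_id[1])
}

#' @rdname read_scenario
#' @param series a `climate_series`.
#' @export
write_scenario <- function(series, path) {
  out <- as.data.frame(series)[c("unit", "date", "tmean")]
  out$model_id <- attr(series, "model_id")
  out$pathway_id <- attr(series, "pathway_id")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
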