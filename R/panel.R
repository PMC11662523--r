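#' Daily municipal mortality-temperature panel
#'
#' A `heat_panel` is a validated data frame with one record per municipality
#' (`unit`) and calendar day (`date`), holding the daily mean temperature
#' `tmean` (degrees C) and the all-cause death count `deaths`. An optional
#' `age65plus_deaths` column carries the 65+ share through to summaries.
#' When a seasonal analysis window is attached, records inside the window are
#' flagged `in_season`; out-of-window records are retained because lagged
#' exposures of early-season days reach back before the window start.
#'
#' @param x data frame with columns `unit`, `date`, `tmean`, `deaths`
#'   (optionally `age65plus_deaths`).
#' @param season `NULL` or character vector `c(start, end)` of month-day
#'   strings (`"05-01"`, `"09-30"`) delimiting the within-year analysis
#'   window, start before end.
#' @return A `heat_panel`: the input sorted by unit and date with a logical
#'   `in_season` column and a `season` attribute.
#' @examples
#' p <- heat_panel(data.frame(unit = "A", date = as.Date("2000-07-01"),
#'                            tmean = 25, deaths = 1L), season = c("05-01", "09-30"))
#' p$in_season
#' @export
heat_panel <- function(x, season = NULL) {
  need <- c("unit", "date", "tmean", "deaths")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    hm_format_error(paste("panel is missing columns:", paste(miss, collapse = ", ")))
  if (nrow(x) == 0) hm_format_error("panel has no records")
  x$unit <- as.character(x$unit)
  x$date <- as.Date(x$date)
  if (anyNA(x$date)) hm_format_error("panel contains unparseable dates")
  if (!all(is.finite(x$tmean))) hm_format_error("tmean must be finite")
  d <- x$deaths
  if (anyNA(d) || any(d < 0) || any(d != round(d)))
    hm_format_error("deaths must be non-negative integers")
  x$deaths <- as.integer(round(d))
  if ("age65plus_deaths" %in% names(x)) {
    a <- x$age65plus_deaths
    if (anyNA(a) || any(a < 0) || any(a != round(a)))
      hm_format_error("age65plus_deaths must be non-negative integers")
    x$age65plus_deaths <- as.integer(round(a))
  }
  key <- paste(x$unit, x$date)
  if (anyDuplicated(key))
    hm_format_error("duplicate (unit, date) records in panel")
  x <- x[order(x$unit, x$date), , drop = FALSE]
  rownames(x) <- NULL
  x$in_season <- season_mask(x$date, season)
  attr(x, "season") <- season
  class(x) <- c("heat_panel", "data.frame")
  x
}

#' @export
print.heat_panel <- function(x, ...) {
  season <- attr(x, "season")
  cat(sprintf("heat_panel: %d records, %d units, %s to %s\n",
              nrow(x), length(unique(x$unit)),
              format(min(x$date)), format(max(x$date))))
  if (!is.null(season))
    cat(sprintf("  season window %s to %s (%d in-season records)\n",
                season[1], season[2], sum(x$in_season)))
  NextMethod()
  invisible(x)
}

# TRUE for dates whose month-day falls inside [season[1], season[2]].
# Month-day strings are zero-padded so lexicographic comparison is calendar
# comparison; only same-year windows (start <= end) are supported.
season_mask <- function(dates, season) {
  if (is.null(season)) return(rep(TRUE, length(dates)))
  if (length(season) != 2)
    hm_config_error("season must be c(start, end) month-day strings")
  if (season[1] > season[2])
    hm_config_error("season window is empty or wraps the year end")
  md <- format(as.Date(dates), "%m-%d")
  md >= season[1] & md <= season[2]
}

#' Read a daily panel from delimited text
#'
#' Reads a comma-delimited file with header
#' `unit,date,tmean,deaths[,age65plus_deaths]` (ISO-8601 dates) and validates
#' it into a [heat_panel()]. With a `season` window, in-season records are
#' flagged but pre-season days are retained for lagged exposures.
#'
#' @param path file path.
#' @inheritParams heat_panel
#' @return A [heat_panel()].
#' @export
read_panel <- function(path, season = NULL) {
  if (!file.exists(path)) hm_format_error(paste("no such file:", path))
  x <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) hm_format_error(paste("cannot parse", path, ":", conditionMessage(e))))
  if (nrow(x) == 0) hm_format_error(paste(path, "contains no records"))
  heat_panel(x, season = season)
}

#' Write a daily panel to delimited text
#'
#' Inverse of [read_panel()]; the `in_season` flag is derived, not stored.
#'
#' @param panel a [heat_panel()].
#' @param path output file path.
#' @export
write_panel <- function(panel, path) {
  keep <- intersect(c("unit", "date", "tmean", "deaths", "age65plus_deaths"),
                    names(panel))
  utils::write.csv(as.data.frame(panel)[, keep, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Daily mean temperature from the daily extremes
#'
#' @param tmin,tmax daily minimum and maximum temperature (degrees C),
#'   elementwise `tmin <= tmax`.
#' @return `(tmin + tmax) / 2`.
#' @examples derive_tmean(10, 30)
#' @export
derive_tmean <- function(tmin, tmax) {
  if (any(tmin > tmax)) hm_value_error("tmin exceeds tmax")
  (tmin + tmax) / 2
}

#' Area-weighted average of grid-cell values
#'
#' Collapses gridded temperatures to one value per municipality using the
#' fraction of each grid cell covered by the municipality as weight.
#'
#' @param values grid-cell values.
#' @param weights non-negative cell weights (area fractions), at least one
#'   positive.
#' @return `sum(weights * values) / sum(weights)`.
#' @examples area_weighted_average(c(10, 20), c(0.25, 0.75))
#' @export
area_weighted_average <- function(values, weights) {
  if (length(values) != length(weights))
    hm_value_error("values and weights differ in length")
  if (any(weights < 0)) hm_value_error("weights must be non-negative")
  if (sum(weights) == 0) hm_value_error("all weights are zero")
  sum(weights * values) / sum(weights)
}
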