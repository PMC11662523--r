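#' Descriptive summary of a panel by area
#'
#' Produces the per-area descriptive table used to characterise the study
#' region: full-year (12-month) and in-season death sums, the seasonal share
#' of deaths, the seasonal 65+ share when an `age65plus_deaths` column is
#' present, and daily-temperature descriptives (mean, range width, IQR) for
#' both the full year and the season. A final region row aggregates all
#' areas; its count columns are exact sums of the area rows, its temperature
#' columns are computed on the pooled records.
#'
#' Percentages are reported to full precision; the IQR is the Q3 - Q1 width
#' with linear-interpolation (type 7) quantiles.
#'
#' @param panel a [heat_panel()] with a season window attached.
#' @param areas data frame with columns `unit`, `area` mapping every unit of
#'   the panel to an area (subregion); a unit absent from the mapping is a
#'   configuration error.
#' @param region_name label for the aggregate row (default `"Region"`).
#' @return data frame with one row per area plus the region row and columns
#'   `area`, `deaths_annual`, `deaths_season`, `season_share_pct`,
#'   (`deaths_season_65plus`, `share_65plus_pct`,) `mean_deaths_day_season`,
#'   `tmean_annual`, `tmean_season`, `trange_annual`, `trange_season`,
#'   `tiqr_season`.
#' @export
summarize_panel <- function(panel, areas, region_name = "Region") {
  if (!inherits(panel, "heat_panel")) panel <- heat_panel(panel)
  if (!all(c("unit", "area") %in% names(areas)))
    hm_config_error("areas must have columns unit and area")
  areas$unit <- as.character(areas$unit)
  unknown <- setdiff(unique(panel$unit), areas$unit)
  if (length(unknown) > 0)
    hm_config_error(paste("units not covered by the area grouping:",
                          paste(unknown, collapse = ", ")))
  panel$area <- areas$area[match(panel$unit, areas$unit)]

  has65 <- "age65plus_deaths" %in% names(panel)
  one <- function(d, label) {
    s <- d[d$in_season, , drop = FALSE]
    n_unit_days <- nrow(s)
    out <- data.frame(
      area = label,
      deaths_annual = sum(d$deaths),
      deaths_season = sum(s$deaths),
      stringsAsFactors = FALSE
    )
    out$season_share_pct <- 100 * out$deaths_season / out$deaths_annual
    if (has65) {
      out$deaths_season_65plus <- sum(s$age65plus_deaths)
      out$share_65plus_pct <- 100 * out$deaths_season_65plus / out$deaths_season
    }
    out$mean_deaths_day_season <- out$deaths_season / n_unit_days
    out$tmean_annual <- mean(d$tmean)
    out$tmean_season <- mean(s$tmean)
    out$trange_annual <- diff(range(d$tmean))
    out$trange_season <- diff(range(s$tmean))
    q <- stats::quantile(s$tmean, c(0.25, 0.75), type = 7, names = FALSE)
    out$tiqr_season <- q[2] - q[1]
    out
  }

  rows <- lapply(split(panel, panel$area), function(d) one(d, d$area[1]))
  res <- do.call(rbind, c(rows, list(one(panel, region_name))))
  rownames(res) <- NULL
  res
}
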