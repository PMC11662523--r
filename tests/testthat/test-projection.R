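test_that("counterfactual deaths replicate seasonal day-of-year means", {
  # single observed year: every projection year repeats its profile
  one <- heat_panel(as.data.frame(
    small_panel[format(small_panel$date, "%Y") == "2000", ]),
    season = c("05-01", "09-30"))
  bd <- baseline_death_series(one, 2050:2051)
  obs <- as.data.frame(one[one$in_season, ])
  key <- paste(obs$unit, format(obs$date, "%m-%d"))
  for (y in c("2050", "2051")) {
    py <- bd[format(bd$date, "%Y") == y, ]
    expect_equal(py$deaths[match(key, paste(py$unit, format(py$date, "%m-%d")))],
                 as.numeric(obs$deaths))
  }
  # two observed years with counts 2 and 4 on May 1 project to 3.0
  toy <- heat_panel(data.frame(
    unit = "u",
    date = as.Date(c("2000-05-01", "2001-05-01", outer(c("2000-", "2001-"),
                     sprintf("05-%02d", 2:12), paste0))),
    tmean = 20,
    deaths = c(2L, 4L, rep(1L, 22))), season = c("05-01", "05-12"))
  bd2 <- baseline_death_series(toy, 2030)
  expect_equal(bd2$deaths[bd2$date == as.Date("2030-05-01")], 3.0)
  expect_equal(bd2$deaths[bd2$date == as.Date("2030-05-02")], 1.0)
  # 3-year fixture against a brute-force day-of-season mean
  three <- heat_panel(as.data.frame(
    small_panel[format(small_panel$date, "%Y") %in% c("1998", "1999", "2000"), ]),
    season = c("05-01", "09-30"))
  bd3 <- baseline_death_series(three, 2042)
  s3 <- as.data.frame(three[three$in_season, ])
  want <- tapply(s3$deaths, paste(s3$unit, format(s3$date, "%m-%d")), mean)
  expect_equal(bd3$deaths,
               as.numeric(want[paste(bd3$unit, format(bd3$date, "%m-%d"))]))
  # total projected deaths are constant across projection years
  bd4 <- baseline_death_series(small_panel, 2040:2043)
  per_year <- tapply(bd4$deaths, format(bd4$date, "%Y"), sum)
  expect_true(all(abs(per_year - per_year[1]) < 1e-9))
  expect_error(baseline_death_series(small_panel, integer(0)),
               class = "heatmort_value_error")
})

make_member <- function(panel, years, shift_per_decade = 0, offset = 0,
                        model = "m", pathway = "p") {
  # deterministic member: repeat each unit's last observed year of
  # temperatures into every target year, plus offset and linear shift
  out <- do.call(rbind, lapply(unique(panel$unit), function(u) {
    h <- as.data.frame(panel[panel$unit == u &
                             format(panel$date, "%Y") == "2005" &
                             !grepl("-02-29", panel$date), ])
    do.call(rbind, lapply(years, function(y) {
      data.frame(unit = u,
                 date = as.Date(paste0(y, format(h$date, "-%m-%d"))),
                 tmean = h$tmean + offset + shift_per_decade * (y - years[1]) / 10)
    }))
  }))
  climate_series(out, model, pathway)
}

test_that("projection impacts respond to warming and average across members", {
  bd <- baseline_death_series(small_panel, 2011:2050)
  periods <- list("2011-2030" = c(2011, 2030), "2031-2050" = c(2031, 2050))
  m0 <- make_member(small_panel, 2011:2050, model = "a")
  m1 <- make_member(small_panel, 2011:2050, offset = 1, model = "b")
  warm <- make_member(small_panel, 2011:2050, shift_per_decade = 0.5, model = "c")

  # a null curve attributes nothing
  red0 <- small_reduced
  red0$eta <- rep(0, length(red0$eta))
  red0$vcov <- matrix(0, length(red0$eta), length(red0$eta))
  pr0 <- suppressWarnings(project_impacts(list(m0), red0, small_mmt$mmt, bd,
                                          periods = periods, n_sim = 20, seed = 1))
  expect_equal(pr0$af_pct, c(0, 0))

  pr <- project_impacts(list(m0, m1), small_reduced, small_mmt$mmt, bd,
                        periods = periods, n_sim = 100, seed = 2)
  me <- attr(pr, "member_estimates")
  # uniformly warmer member has strictly larger attributable numbers
  expect_true(all(me$an[me$model == "b"] > me$an[me$model == "a"]))
  # ensemble mean equals the arithmetic mean of member point estimates
  for (pn in names(periods)) {
    expect_equal(pr$af_pct[pr$period == pn],
                 mean(me$af_pct[me$period == pn]), tolerance = 1e-12)
  }
  expect_true(all(pr$n_members == 2))

  # warming scenario: later periods have larger impacts; stationary does not
  prw <- project_impacts(list(warm), small_reduced, small_mmt$mmt, bd,
                         periods = periods, n_sim = 50, seed = 3)
  expect_gt(prw$af_pct[prw$period == "2031-2050"],
            prw$af_pct[prw$period == "2011-2030"])
  prs <- project_impacts(list(m0), small_reduced, small_mmt$mmt, bd,
                         periods = periods, n_sim = 50, seed = 4)
  expect_lt(abs(prs$af_pct[1] - prs$af_pct[2]), 0.5)
})

test_that("a stationary member reproduces the historical impact", {
  # member equal to the observed 2005 temperatures, counterfactual deaths:
  # projected fraction matches the attribution fraction on the same inputs
  bd <- baseline_death_series(small_panel, 2011:2030)
  m0 <- make_member(small_panel, 2011:2030)
  pr <- project_impacts(list(m0), small_reduced, small_mmt$mmt, bd,
                        periods = list("2011-2030" = c(2011, 2030)),
                        n_sim = 200, seed = 5)
  hist <- aggregate_attribution(
    attribute_panel(small_panel, small_reduced, small_mmt$mmt))
  # same curve, same climate regime: the projected relative excess is close
  # to the historical one (the member repeats one specific observed year)
  expect_lt(abs(pr$af_pct - hist$af_total_pct), 5)
  expect_true(pr$eci_lo <= pr$af_pct && pr$af_pct <= pr$eci_hi)
})

test_that("members not spanning a period are excluded with a warning", {
  bd <- baseline_death_series(small_panel, 2011:2030)
  short <- make_member(small_panel, 2011:2020)
  expect_warning(
    pr <- project_impacts(list(short), small_reduced, small_mmt$mmt, bd,
                          periods = list("2011-2030" = c(2011, 2030),
                                         "2011-2020" = c(2011, 2020)),
                          n_sim = 20, seed = 6),
    "does not cover")
  expect_equal(pr$period, "2011-2020")
  expect_error(suppressWarnings(
    project_impacts(list(short), small_reduced, small_mmt$mmt, bd,
                    periods = list("2031-2050" = c(2031, 2050)),
                    n_sim = 20, seed = 7)),
    class = "heatmort_value_error")
})
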