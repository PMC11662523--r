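# heatmort

Heat kills, and it kills on a schedule: when daily mean temperature rises
above a region-specific optimum, all-cause mortality climbs within days and
stays elevated for up to a week or more. `heatmort` is an R package for
quantifying that relationship in panels of small areas (municipalities)
with very low daily death counts, and for projecting the resulting burden
to the end of the century under climate-change scenarios. It is aimed at
environmental epidemiologists and public-health analysts who need the full
chain — exposure-response estimation, attribution, bias-corrected
projections — in one tested toolbox, together with a synthetic-data
generator whose ground truth lets every stage be validated.

## The model

Daily counts $y_{it}$ for municipality $i$ follow a conditional Poisson
*case time series* model,

$$\log \mu_{it} \;=\; \alpha_{s(i,t)} \;+\; \sum_{\ell=0}^{10}
f(x_{i,t-\ell}, \ell),$$

with strata $s$ = municipality × year × month absorbing baseline risk,
trends and seasonality; conditioning on stratum totals eliminates the
$\alpha_s$ exactly. The exposure-lag surface $f$ is a distributed lag
non-linear model (DLNM): a tensor-product cross-basis of natural cubic
splines in temperature (knots at the 10/25/50/75/90th in-season
percentiles) and in lag (0–10 days, log-spaced knots). From the fit the
package derives the overall cumulative relative risk curve, its minimum
(the minimum mortality temperature, MMT), forward attributable fractions
and numbers restricted to heat,

$$\mathrm{AF}_t = 1 - e^{-c_t}, \qquad
\mathrm{AN}_t = \mathrm{AF}_t \cdot \overline{y}_{t..t+10},$$

Monte Carlo empirical confidence intervals from coefficient draws,
trend-preserving month-wise bias correction of climate-model temperatures,
and 20-year-period projections with ensemble averaging. The methods
vignette (`vignettes/heatmort-methods.Rmd`) documents every modelling and
numerical choice.

## Worked example

```r
library(heatmort)

cfg <- synth_config(n_units = 6, year_start = 1996, year_end = 2005, seed = 7)
panel <- generate_panel(cfg)          # daily temperature + deaths, known truth
model <- fit_heat_model(panel)        # cross-basis + conditional Poisson
reduced <- reduce_to_overall(model$fit)
mmt <- find_mmt(reduced, temps = panel$tmean[panel$in_season])

model$fit
#> cts_fit: 24 coefficients, 9180 observations, 300/300 informative strata
#>   conditional log-likelihood -12561.6598, converged: TRUE (5 iterations)

round(mmt$mmt, 2)
#> [1] 19.07        # true minimum mortality temperature: 19

predict_cumulative(model$fit, model$spec, c(22, 26, 30), reference = mmt$mmt)
#>   temp log_rr    se    rr rr_lo rr_hi
#> 1   22  0.345 0.139 1.412 1.074 1.855
#> 2   26  0.575 0.115 1.777 1.420 2.225
#> 3   30  1.038 0.180 2.823 1.983 4.018

attribute_with_eci(panel, reduced, mmt$mmt, n_sim = 1000, seed = 1)
#>    window measure   estimate    eci_lo     eci_hi
#> 1 overall      an 1195.24845 758.23638 1522.86770
#> 2 overall  af_pct   32.43551  20.57629   41.32612
```

Reading the output: the fit used 9,180 in-season municipality-days in 300
informative strata; the estimated MMT of 19.07 °C recovers the generator's
true 19 °C; the cumulative relative risk reaches 2.8 (95% CI 2.0–4.0) at
30 °C, i.e. a 182% increase over the optimum; and 1,195 deaths — 32.4%
(95% eCI 20.6–41.3%) of all in-season deaths in this strongly-dosed toy
panel — are attributable to heat. On the generator's study-scale defaults
the same pipeline recovers the true MMT with a median absolute error
below 1 °C.

Scenario projection follows the same pattern: `generate_scenario()` (or
`read_scenario()`), `fit_correction()`/`apply_correction()`,
`baseline_death_series()`, then `project_impacts()` for period × pathway
tables, and `compare_heat_risk()` for subperiod contrasts.

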