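---
title: "Modelling heat-related mortality with heatmort: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heat-related mortality with heatmort: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`heatmort` quantifies the short-term effect of ambient heat on daily
all-cause mortality in panels of small areas (municipalities) and projects
the attributable burden under climate-change scenarios. This vignette
explains the statistical model, the package's tunable parameters and
defaults, what the synthetic-data generator does and does not emulate, the
numerical choices, and the known limitations.

## The case time series model

Each municipality contributes a daily series of death counts $y_{it}$ and
mean temperatures $x_{it}$. Counts are modelled as overdispersed-free
Poisson with a stratum-specific baseline and a distributed-lag non-linear
term:

$$y_{it} \sim \mathrm{Poisson}(\mu_{it}), \qquad
\log \mu_{it} = \alpha_{s(i,t)} + \sum_{\ell=0}^{L} f(x_{i,t-\ell}, \ell),$$

where $s(i,t)$ indexes strata formed by municipality × year × calendar
month (the *case time series* design). Conditioning each stratum on its
total count eliminates the $\alpha_s$ nuisance parameters exactly: within a
stratum the counts are multinomial with probabilities proportional to
$\exp(x_{it}'\beta)$, and the conditional likelihood maximiser coincides
with an unconditional Poisson fit carrying one indicator per stratum. The
stratification absorbs every between-stratum confounder — long-term trends,
seasonality at monthly resolution, and all time-invariant differences
between municipalities. What it cannot absorb is confounding *within* a
month, which is why the synthetic-data tests include a within-month
seasonal gradient (see Limitations).

The exposure-lag surface $f$ is a tensor product ("cross-basis") of a
natural cubic spline in temperature and a natural cubic spline in lag
(0–10 days, intercept plus two internal knots equally spaced on the log
lag scale). Row $t$ of the design is
$\sum_{\ell=0}^{L} b_{\mathrm{var}}(x_{t-\ell}) \otimes b_{\mathrm{lag}}(\ell)$,
with the temperature index varying fastest; predictions are invariant to
this documented ordering. Rows whose lag window crosses the start of a
series or a date gap are flagged invalid and excluded from the fit rather
than imputed.

### Temperature knots

The default temperature basis places internal knots at the 10th, 25th,
50th, 75th and 90th percentiles of the pooled in-season distribution, with
boundary knots at the observed range. Placing knots only in the upper half
(e.g. at the 50th/90th, or the 50/75/90, 50/75 and 75/90 variants kept
available through `var_percentiles` for sensitivity analysis) leaves the
long segment below the median effectively linear, and a spline that cannot
bend below the median cannot place a risk minimum there: in simulation the
fitted minimum then collapses to the search-window edge regardless of
sample size. Regions of the kind this package targets have minimum
mortality temperatures well below the seasonal median, so the default
spends two of its five knots on the lower tail — the P10 knot familiar
from the multi-country DLNM literature plus the lower quartile. With this
default, study-scale simulations recover a true minimum at 19 °C with a
median absolute error well under 1 °C.

### Minimum mortality temperature

The MMT is the grid argmin of the cumulative (lag-summed) log relative
risk over a search window, by default the 1st–99th percentile of in-season
temperatures so that noisy tails cannot drive the minimum. The scan uses a
0.1 °C grid and two passes: the curve is centred at a provisional
reference (window midpoint), re-centred at the provisional minimiser, and
scanned once more. Because the conditional fit itself is centre-invariant,
re-centring changes only the reporting reference, never the fit; the
two-pass scheme guards the numerical search. A minimiser on the window
edge is returned with a boundary flag and warning — it means the curve is
monotone over the window and no interior optimum exists.

### Lag-dimension reduction and extrapolation

Cumulative predictions are linear in $\eta = M\beta$, where $M$ sums the
lag basis over 0..L; `reduce_to_overall()` returns $\eta$ and
$M V M^\top$, and reproduces full-fit cumulative predictions to numerical
precision. Natural cubic splines are linear beyond their boundary knots,
so predicting from the reduced fit at warmer-than-observed temperatures
continues the curve log-linearly with the boundary slope — exactly the
tail behaviour needed when projecting onto future climates, at the price
of ignoring functional-form uncertainty out there (see Limitations).

## Attribution

The forward attributable fraction of day $t$ is
$\mathrm{AF}_t = 1 - \exp(-c_t)$, with $c_t$ the cumulative log relative
risk of the day's exposure versus the MMT; the burden is restricted to
heat, so $\mathrm{AF}_t = 0$ at or below the reference. Tiny negative
$c_t$ just above a grid-searched reference are truncated at zero so
fractions stay in $[0,1)$. The attributable number applies the fraction to
the mean deaths over the forward window $t..t+L$; each unit-year seasonal
block is one contiguous series, windows never reach across the off-season
break, and trailing days average over the remaining in-season days and are
flagged. Window totals are exactly additive over partitions by
construction.

Empirical 95% confidence intervals draw coefficient vectors from
$N(\eta, V_\eta)$ (1000 draws by default), recompute every requested total
per draw, and take the 2.5/97.5 empirical percentiles. One set of draws is
shared across windows so that annual series and window totals stay
coherent. Covariances that fail a Cholesky factorisation are symmetrised
and eigenvalue-clipped at zero with a warning. Whether per-draw
recomputation should also re-locate the MMT is genuinely open; the package
holds the reference fixed across draws, so the intervals quantify
coefficient uncertainty given the chosen reference.

## Bias correction of scenario temperatures

Scenario members are calibrated month-wise per unit: the additive offset
is observed minus modelled historical monthly mean; the residual scale is
the ratio of within-month standard deviations, residuals taken about each
year's own monthly mean. Application re-expresses each daily value about
its unit-year-month mean, so interannual variability and the long-term
change signal pass through the additive channel untouched — the
trend-preserving property, exact for monthly means by construction. This
is the month-wise parametric variant of the trend-preserving approach;
the day-windowed transfer-function variant is out of scope. Months with
zero model variance get scale 1 with a warning; correction is strictly
increasing in the daily value, so within-month rank order is preserved.

## Projection

Counterfactual death series replicate the observed mean count per
seasonal day-of-year (aligned by month-day; February 29 never occurs in a
May–September season) identically into every projection year, so
projected totals per year are constant — demographic change is explicitly
not modelled. Impacts are computed per ensemble member with the
(extrapolated) reduced fit, aggregated into 20-year periods
(1981–2000 … 2081–2100), and averaged across members within a pathway.
Interval estimates pool the Monte Carlo coefficient draws across members
into one empirical distribution per pathway-period, reflecting both
coefficient uncertainty and inter-member spread. Corrected member
temperatures are used for all periods, including the historical ones, so
that periods differ only through the climate signal.

## Subperiod comparisons

Temporal (first half vs second half) and seasonal (May–June vs
July–September) contrasts refit the model on each subset with one *shared*
knot specification derived from the pooled full-period temperatures, and
report cumulative relative risks at the 50/75/95/99th pooled percentiles
against one shared reference (the regional MMT). Sharing basis and
reference isolates coefficient differences from basis differences and
makes curves directly comparable; both subset curves equal 1 at the shared
reference by construction. Differences are tested on the log relative risk
scale with $z = (\log RR_a - \log RR_b)/\sqrt{se_a^2 + se_b^2}$ — the
standard interaction test for ratios from independent subsets, consistent
with delta-method log-scale standard errors.

## The synthetic-data generator

The generator exists so that every stage can be validated against known
ground truth without restricted mortality microdata. It emulates:

* **Low daily counts.** Poisson deaths at 0.3 expected deaths per
  municipality-day, so most municipal days have zero deaths — the regime
  that motivates stratum conditioning rather than per-series regression.
* **A J-shaped exposure response.** On the log-risk scale the true surface
  is V-shaped: linear in temperature above the true minimum
  (default `slope_true` = 0.04 per °C at lag 0) and linear with half that
  slope below it. The shallow cold arm is what makes the minimum an
  identifiable interior point: with a perfectly flat cold side the argmin
  of any smooth fit is undetermined over the flat region and collapses to
  the search boundary. The 2:1 asymmetry keeps the heat side dominant, as
  in observed summer-season curves. Lag effects decay geometrically
  (ratio 0.6 over lags 0–10), giving several days of persisting excess.
* **Regional climate.** An annual sinusoid (mean 16.6 °C, amplitude
  8.2 °C, peak at day 206) plus per-unit offsets spanning −2..+2 °C
  (coastal-to-inland contrast), AR(1) noise (lag-1 correlation 0.75,
  innovation sd 1.7) and 0.2 °C/decade warming. These values reproduce
  the descriptive statistics of a warm southern-European region: annual
  mean ≈ 16.6 °C, seasonal (May–September) mean ≈ 22 °C, seasonal maxima
  in the mid-thirties.
* **Confounded baselines.** Mean-one lognormal stratum factors
  (sd 0.2 per unit-year-month), winter-peaking baseline seasonality
  (log-amplitude 0.15) and a −0.05/decade secular trend. The seasonal
  gradient correlates negatively with temperature, so an unstratified
  Poisson fit is visibly attenuated while the conditional fit is not —
  the generator genuinely exercises the conditional likelihood.
* **Scenario members.** Daily series built from the reference day-of-year
  climatology plus a configured additive bias, variance-inflated AR(1)
  noise and a linear warming trend; members from one seed share their
  noise, so pathways differ only through warming. The packaged study
  conditions use five members per pathway with biases between −1.5 and
  +1.6 °C, scale factors 0.9–1.2, and 0.45 (no-mitigation) vs 0.18
  (mitigation) °C/decade.

It does **not** emulate: age/sex structure (only a pass-through 65+ count
column for summaries), spatial correlation between municipalities beyond
shared seasonality, humidity or pollution co-exposures, non-linear warming
trajectories, or cause-of-death coding (the exclusion of external-cause
chapters is emulated by an optional binomial thinning fraction). Passing
tests therefore demonstrate correctness of the estimation machinery under
a known, simplified data-generating process — not robustness to every
feature of real mortality data.

Because the generating surface is piecewise linear while the fit is a
smooth spline, the fitted curve smooths the kink at the minimum; this is
visible as a few-percent downward bias of the cumulative curve at
moderate temperatures and is the reason some validation checks are framed
as medians over replicates with explicit tolerances.

## Numerical choices

* Newton–Raphson with step-halving on the conditional log-likelihood;
  convergence requires a relative log-likelihood change < 1e-9 and a small
  gradient (1e-6, scaled with the total death count so the criterion
  remains attainable in double precision on panels with ~10^5 deaths);
  iteration cap 100, non-convergence flagged rather than raised. The
  covariance is the inverse observed information, symmetrised; singular
  information falls back to a ridged inverse with a warning.
* Per-stratum log-sum-exp shifts guard the conditional likelihood against
  overflow.
* Quantiles (knots, percentile comparisons, the IQR = Q3 − Q1 convention
  in summaries) use linear-interpolation type-7 quantiles throughout.
* Strata with zero total deaths contribute nothing to the likelihood and
  are dropped; the count of informative strata is reported.
* The MMT grid step is 0.1 °C; the fine-grid oracle in the tests confirms
  the scan is within one step of an exhaustive 0.01 °C search.

## Validation problem sizes

The shipped test-suite exercises the pipeline at three scales, chosen to
probe different error regimes: small panels (5–8 municipalities, 3–8
years) for oracle equivalences, calibration of the Z-test (200 null
splits) and interval coverage, where sampling uncertainty dominates;
study-scale panels (47 municipalities × 36 years, 20 replicates) for
recovery of the minimum mortality temperature (median absolute error
required ≤ 1 °C) and of the cumulative curve at ten degrees above the
optimum (median relative error ≤ 15%); and a ten-member ensemble spanning
1981–2100 for projection behaviour.

## Known limitations

* **Empirical intervals carry coefficient uncertainty only.** At study
  scale (hundreds of thousands of deaths) the sampling uncertainty
  becomes so small that the spline's approximation bias of the kinked
  generating surface dominates: the true attributable fraction then falls
  outside the empirical interval even though the relative error is modest.
  Coverage checks are therefore run on panels where sampling uncertainty
  dominates. The same caveat applies to real analyses: the intervals do
  not include functional-form uncertainty, notably for the extrapolated
  tail.
* Attenuation from within-stratum (within-month) confounding is not
  removed by design; with the generator's defaults it contributes a few
  percent of downward bias.
* No overdispersion adjustment is fitted, matching the reporting
  convention of the design this package implements.
* Projections hold demography and adaptation fixed; they answer "what
  would today's population experience under tomorrow's climate".
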