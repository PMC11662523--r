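# Shared fixtures: one small synthetic panel with its fitted model, reused
# across test files. All randomness is seeded through the configs.

small_cfg <- synth_config(n_units = 6, year_start = 1998, year_end = 2005,
                          seed = 42)
small_panel <- generate_panel(small_cfg)
small_model <- fit_heat_model(small_panel)
small_reduced <- reduce_to_overall(small_model$fit)
small_mmt <- find_mmt(small_reduced,
                      temps = small_panel$tmean[small_panel$in_season])

# independent brute-force cross-basis: explicit double sum over lags
brute_crossbasis <- function(x, spec) {
  Bv <- natural_cubic_basis(x, spec$var_knots, spec$var_boundary)
  Bl <- if (spec$lag_max == 0) matrix(1, 1, 1) else {
    b <- natural_cubic_basis(0:spec$lag_max, spec$lag_knots, c(0, spec$lag_max))
    if (spec$lag_intercept) cbind(1, b) else b
  }
  pv <- ncol(Bv); pl <- ncol(Bl); n <- length(x)
  out <- matrix(NA_real_, n, pv * pl)
  for (t in seq_len(n)) {
    if (t <= spec$lag_max) next
    acc <- matrix(0, pv, pl)
    for (l in 0:spec$lag_max)
      acc <- acc + outer(Bv[t - l, ], Bl[l + 1, ])
    out[t, ] <- as.numeric(acc)   # var index fastest
  }
  out
}
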