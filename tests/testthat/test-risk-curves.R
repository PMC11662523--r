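test_that("cumulative curve is centred and matches direct arithmetic", {
  fit <- small_model$fit
  spec <- small_model$spec
  ref <- 20
  grid <- c(18, ref, 24, 29)
  curve <- predict_cumulative(fit, spec, grid, reference = ref)
  # exact centring at the reference
  at_ref <- curve[curve$temp == ref, ]
  expect_equal(at_ref$rr, 1)
  expect_equal(at_ref$se, 0)
  expect_equal(at_ref$rr_lo, 1)
  expect_equal(at_ref$rr_hi, 1)
  expect_equal(curve$rr, exp(curve$log_rr))
  expect_true(all(curve$rr_lo <= curve$rr & curve$rr <= curve$rr_hi))
  # independent arithmetic: basis-difference dot products built from parts
  Bl <- cbind(1, natural_cubic_basis(0:spec$lag_max, spec$lag_knots,
                                     c(0, spec$lag_max)))
  lagsum <- colSums(Bl)
  for (tg in grid) {
    dv <- as.numeric(natural_cubic_basis(tg, spec$var_knots, spec$var_boundary)) -
      as.numeric(natural_cubic_basis(ref, spec$var_knots, spec$var_boundary))
    want <- sum(as.numeric(outer(dv, lagsum)) * fit$beta)
    expect_equal(curve$log_rr[curve$temp == tg], want, tolerance = 1e-12)
  }
  expect_error(predict_cumulative(fit, spec, numeric(0), ref),
               class = "heatmort_value_error")
})

test_that("confidence width scales with the coefficient covariance", {
  fit2 <- small_model$fit
  fit2$vcov <- 2 * fit2$vcov
  c1 <- predict_cumulative(small_model$fit, small_model$spec, 28, reference = 20)
  c2 <- predict_cumulative(fit2, small_model$spec, 28, reference = 20)
  expect_equal(c2$se, sqrt(2) * c1$se, tolerance = 1e-12)
})

test_that("lag reduction reproduces the full cumulative prediction", {
  red <- small_reduced
  grid <- seq(15, 32, length.out = 50)
  full <- predict_cumulative(small_model$fit, small_model$spec, grid, reference = 20)
  from_red <- predict_reduced(red, grid, reference = 20)
  expect_equal(from_red$log_rr, full$log_rr, tolerance = 1e-8)
  expect_equal(from_red$se, full$se, tolerance = 1e-8)
})

test_that("lag reduction is the identity when the lag window is a point", {
  x <- small_panel$tmean
  spec0 <- knot_spec(small_panel$tmean[small_panel$in_season], lag_max = 0)
  cb <- build_crossbasis(small_panel, spec0)
  str <- assign_strata(small_panel, crossbasis = cb)
  fit0 <- fit_conditional_poisson(cb, small_panel$deaths, str,
                                  subset = small_panel$in_season)
  red0 <- reduce_to_overall(fit0)
  expect_equal(red0$eta, fit0$beta)
  expect_equal(red0$vcov, fit0$vcov)
})

test_that("reduced covariance matches resampled full-fit predictions", {
  # Monte Carlo oracle: spread of cumulative predictions under draws of the
  # full coefficient vector vs the reduced-fit delta-method standard errors
  set.seed(99)
  fit <- small_model$fit
  n_draw <- 10000
  B <- matrix(rnorm(n_draw * length(fit$beta)), n_draw) %*% chol(fit$vcov) +
    matrix(fit$beta, n_draw, length(fit$beta), byrow = TRUE)
  grid <- c(24, 27, 30)
  G <- t(apply(B, 1, function(b) {
    f <- fit; f$beta <- b
    predict_cumulative(f, small_model$spec, grid, reference = 20)$log_rr
  }))
  emp_sd <- apply(G, 2, sd)
  red_se <- predict_reduced(small_reduced, grid, reference = 20)$se
  expect_equal(emp_sd, red_se, tolerance = 0.05)
})

test_that("minimum mortality temperature equals a fine-grid scan", {
  temps <- small_panel$tmean[small_panel$in_season]
  mm <- find_mmt(small_reduced, temps = temps, step = 0.1)
  w <- unname(quantile(temps, c(0.01, 0.99)))
  fine <- seq(w[1], w[2], by = 0.01)
  lr <- predict_reduced(small_reduced, fine, reference = mean(w))$log_rr
  expect_lt(abs(mm$mmt - fine[which.min(lr)]), 0.1 + 1e-9)
  expect_false(mm$boundary)
})

test_that("a monotone curve pushes the minimum to the window edge", {
  # coefficients chosen so the curve is exactly linear in temperature
  spec <- small_model$spec
  grid <- seq(12, 32, by = 0.5)
  B <- natural_cubic_basis(grid, spec$var_knots, spec$var_boundary)
  eta <- unname(stats::coef(stats::lm(grid ~ B))[-1])
  red <- list(eta = eta, vcov = diag(1e-6, length(eta)), spec = spec)
  class(red) <- "reduced_fit"
  expect_warning(mm <- find_mmt(red, window = c(15, 30)), "edge")
  expect_equal(mm$mmt, 15)
  expect_true(mm$boundary)
})

test_that("relative risks convert to percent increases", {
  expect_equal(percent_increase(5.13), 413)
  expect_equal(percent_increase(1.62), 62)
  expect_equal(percent_increase(1), 0)
  expect_error(percent_increase(0), class = "heatmort_value_error")
})

test_that("the curve extends log-linearly beyond the observed range", {
  red <- small_reduced
  hi <- red$spec$var_boundary[2]
  inside <- c(hi - 3, hi - 1)
  expect_equal(extrapolate_curve(red, inside, reference = 20),
               predict_reduced(red, inside, reference = 20)$log_rr)
  # equally spaced points beyond the boundary give constant differences
  beyond <- hi + c(1, 2, 3, 4)
  lr <- extrapolate_curve(red, beyond, reference = 20)
  expect_equal(diff(lr)[1], diff(lr)[2], tolerance = 1e-9)
  expect_equal(diff(lr)[2], diff(lr)[3], tolerance = 1e-9)
  # tail slope equals the boundary derivative (finite-difference oracle)
  dlt <- 1e-4
  slope_fd <- (extrapolate_curve(red, hi, 20) -
               extrapolate_curve(red, hi - dlt, 20)) / dlt
  expect_equal(diff(lr)[1], slope_fd, tolerance = 1e-5)
})

test_that("lag-specific risks are centred and sum to the cumulative", {
  fit <- small_model$fit
  spec <- small_model$spec
  at_ref <- lag_response(fit, spec, temp = 20, reference = 20)
  expect_equal(at_ref$rr, rep(1, spec$lag_max + 1))
  lr <- lag_response(fit, spec, temp = 29, reference = 20)
  cum <- predict_cumulative(fit, spec, 29, reference = 20)
  expect_equal(sum(lr$log_rr), cum$log_rr, tolerance = 1e-10)
  # lag-0 value equals the direct dot product
  dv <- as.numeric(natural_cubic_basis(29, spec$var_knots, spec$var_boundary)) -
    as.numeric(natural_cubic_basis(20, spec$var_knots, spec$var_boundary))
  bl0 <- c(1, natural_cubic_basis(0, spec$lag_knots, c(0, spec$lag_max)))
  expect_equal(lr$log_rr[1], sum(as.numeric(outer(dv, bl0)) * fit$beta),
               tolerance = 1e-12)
})

test_that("the fitted curve is invariant to affine exposure rescaling", {
  to_f <- function(x) x * 9 / 5 + 32
  spec_c <- small_model$spec
  spec_f <- knot_spec(var_knots = to_f(spec_c$var_knots),
                      var_boundary = to_f(spec_c$var_boundary),
                      lag_max = spec_c$lag_max, lag_knots = spec_c$lag_knots)
  pf <- small_panel
  pf$tmean <- to_f(pf$tmean)
  cbf <- build_crossbasis(pf, spec_f)
  strf <- assign_strata(pf, crossbasis = cbf)
  fitf <- fit_conditional_poisson(cbf, pf$deaths, strf, subset = pf$in_season)
  grid_c <- c(22, 26, 30)
  rr_c <- predict_cumulative(small_model$fit, spec_c, grid_c, reference = 20)$rr
  rr_f <- predict_cumulative(fitf, spec_f, to_f(grid_c), reference = to_f(20))$rr
  expect_equal(rr_f, rr_c, tolerance = 1e-6)
})
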