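#' Assign case time series strata
#'
#' Baseline mortality in the case time series design is absorbed by
#' conditioning within strata. The full scheme interacts unit, calendar
#' year and calendar month (`"A:1980:07"`); the reduced scheme drops the
#' monthly component. Records flagged invalid by a cross-basis (incomplete
#' lag history) receive `NA` and are excluded downstream.
#'
#' @param panel a [heat_panel()].
#' @param scheme `"unit_year_month"` (default) or `"unit_year"`.
#' @param crossbasis optional [build_crossbasis()] result aligned with the
#'   panel rows; its invalid rows are set to `NA`.
#' @return factor of stratum labels, one per panel row (`NA` = excluded).
#' @export
assign_strata <- function(panel, scheme = c("unit_year_month", "unit_year"),
                          crossbasis = NULL) {
  scheme <- match.arg(scheme)
  y <- format(panel$date, "%Y")
  lab <- if (scheme == "unit_year_month") {
    paste(panel$unit, y, format(panel$date, "%m"), sep = ":")
  } else {
    paste(panel$unit, y, sep = ":")
  }
  if (!is.null(crossbasis)) lab[!crossbasis$valid] <- NA
  factor(lab)
}

#' Conditional Poisson regression on a cross-basis
#'
#' Fits the case time series model: within each stratum, daily counts
#' conditional on the stratum total are multinomial with probabilities
#' proportional to `exp(x_i' beta)`, which eliminates the stratum-specific
#' baseline rates. The conditional log-likelihood (up to a beta-free
#' constant) is
#' `sum_s [ sum_i y_i x_i' beta - Y_s log sum_i exp(x_i' beta) ]`;
#' strata with zero total deaths contribute nothing and are dropped. The
#' maximiser coincides with an unconditional Poisson fit that carries one
#' indicator per stratum.
#'
#' Newton-Raphson with step-halving on the analytic gradient and observed
#' information; convergence requires a relative log-likelihood change below
#' `1e-9` together with a small gradient (tolerance `1e-6`, scaled up with
#' the total death count to keep it attainable in double precision on large
#' panels), within 100 iterations. The covariance is the inverse observed
#' information at the optimum.
#'
#' @param crossbasis a [build_crossbasis()] object or plain design matrix.
#' @param deaths integer counts aligned with the design rows.
#' @param strata factor aligned with the design rows; `NA` rows are
#'   excluded.
#' @param subset optional logical vector selecting rows to fit on (e.g. the
#'   in-season flag); invalid cross-basis rows are always excluded.
#' @return A `cts_fit`: list with `beta`, `vcov`, `loglik`, `converged`,
#'   `iter`, `n_strata_total`, `n_strata_informative`, `n_obs`, and the
#'   `spec` when the design was a cross-basis.
#' @export
fit_conditional_poisson <- function(crossbasis, deaths, strata, subset = NULL) {
  spec <- NULL
  if (inherits(crossbasis, "crossbasis")) {
    X <- crossbasis$matrix
    keep <- crossbasis$valid
    spec <- crossbasis$spec
  } else {
    X <- as.matrix(crossbasis)
    keep <- rep(TRUE, nrow(X))
  }
  if (length(deaths) != nrow(X) || length(strata) != nrow(X))
    hm_value_error("deaths and strata must align with the design rows")
  keep <- keep & !is.na(strata)
  if (!is.null(subset)) keep <- keep & subset
  X <- X[keep, , drop = FALSE]
  y <- deaths[keep]
  str <- droplevels(factor(strata[keep]))
  n_total <- nlevels(str)

  Ys <- rowsum(y, str, reorder = FALSE)[, 1]
  informative <- names(Ys)[Ys > 0]
  if (length(informative) == 0) hm_fit_error("no informative strata")
  sel <- str %in% informative
  X <- X[sel, , drop = FALSE]
  y <- y[sel]
  str <- droplevels(str[sel])
  si <- as.integer(str)
  Ys <- rowsum(y, si, reorder = TRUE)[, 1]

  p <- ncol(X)
  beta <- numeric(p)
  Xty <- crossprod(X, y)
  gtol <- 1e-6 * max(1, sum(y) * 1e-4)

  loglik <- function(eta) {
    m <- tapply_max(eta, si, nlevels(str))
    w <- exp(eta - m[si])
    Ws <- rowsum(w, si, reorder = TRUE)[, 1]
    list(ll = sum(y * eta) - sum(Ys * (log(Ws) + m)), w = w, Ws = Ws)
  }

  eta <- as.numeric(X %*% beta)
  st <- loglik(eta)
  ll_old <- st$ll
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    P <- st$w / st$Ws[si]
    d <- Ys[si] * P
    g <- Xty - crossprod(X, d)
    mu <- rowsum(P * X, si, reorder = TRUE)          # stratum-wise weighted means
    info <- crossprod(X, d * X) - crossprod(sqrt(Ys) * mu)
    step <- tryCatch(solve(info, g), error = function(e) {
      solve(info + diag(1e-8 * max(diag(info)) + 1e-12, p), g)
    })
    # step-halving until the likelihood does not decrease
    lam <- 1
    repeat {
      beta_new <- beta + lam * step
      eta_new <- as.numeric(X %*% beta_new)
      st_new <- loglik(eta_new)
      if (is.finite(st_new$ll) && st_new$ll >= ll_old - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { st_new <- st; beta_new <- beta; break }
    }
    beta <- beta_new
    st <- st_new
    rel <- abs(st$ll - ll_old) / (abs(ll_old) + 1e-10)
    ll_old <- st$ll
    if (rel < 1e-9 && max(abs(g)) < gtol) { converged <- TRUE; break }
    if (iter >= 100) break
  }

  # observed information at the optimum
  P <- st$w / st$Ws[si]
  d <- Ys[si] * P
  mu <- rowsum(P * X, si, reorder = TRUE)
  info <- crossprod(X, d * X) - crossprod(sqrt(Ys) * mu)
  vcov <- tryCatch(solve(info), error = function(e) {
    warning("information matrix singular; ridged inverse used")
    solve(info + diag(1e-8 * max(diag(info)), p))
  })
  vcov <- (vcov + t(vcov)) / 2

  if (!converged)
    warning(sprintf("conditional Poisson fit did not converge in %d iterations", iter))
  out <- list(beta = as.numeric(beta), vcov = vcov, loglik = st$ll,
              converged = converged, iter = iter,
              n_strata_total = n_total,
              n_strata_informative = length(informative),
              n_obs = length(y), spec = spec)
  class(out) <- "cts_fit"
  out
}

# fast per-group maximum for the log-sum-exp shift
tapply_max <- function(x, group, ngroup) {
  m <- rep(-Inf, ngroup)
  o <- order(group, x)
  m[group[o]] <- x[o]   # last assignment per group is its maximum
  m
}

#' @export
print.cts_fit <- function(x, ...) {
  cat(sprintf("cts_fit: %d coefficients, %d observations, %d/%d informative strata\n",
              length(x$beta), x$n_obs, x$n_strata_informative, x$n_strata_total))
  cat(sprintf("  conditional log-likelihood %.4f, converged: %s (%d iterations)\n",
              x$loglik, x$converged, x$iter))
  invisible(x)
}

#' Fit the full heat-mortality model on a panel
#'
#' Convenience pipeline: derives the knot specification from the in-season
#' temperature distribution (unless given), builds the cross-basis per unit,
#' assigns strata, and fits the conditional Poisson regression on the valid
#' in-season records.
#'
#' @param panel a [heat_panel()] with a season window.
#' @param spec optional [knot_spec()]; default derived from the in-season
#'   pooled temperatures with the package defaults.
#' @param scheme stratum scheme, see [assign_strata()].
#' @param ... passed to [knot_spec()] when `spec` is `NULL`.
#' @return list with elements `fit` ([fit_conditional_poisson()] result),
#'   `spec`, `crossbasis`, `strata` and the `panel`.
#' @export
fit_heat_model <- function(panel, spec = NULL,
                           scheme = c("unit_year_month", "unit_year"), ...) {
  scheme <- match.arg(scheme)
  if (is.null(spec)) spec <- knot_spec(panel$tmean[panel$in_season], ...)
  cb <- build_crossbasis(panel, spec)
  str <- assign_strata(panel, scheme, crossbasis = cb)
  fit <- fit_conditional_poisson(cb, panel$deaths, str, subset = panel$in_season)
  list(fit = fit, spec = spec, crossbasis = cb, strata = str, panel = panel)
}
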