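## Projection of the period and cohort indices with ARIMA processes, and
## assembly of bootstrap indicator curves and percentile intervals.
## Orders are chosen once, by corrected-AIC over a small Box-Jenkins grid,
## on the indices fitted to the original data, and held fixed when the
## coefficients are refitted on every bootstrap replicate.  Forecasts are
## conditional means: interval uncertainty comes only from the bootstrap
## parameter error.

#' Select an ARIMA specification by corrected AIC
#'
#' Fits every candidate order on a small grid (`p, q` in `0..2`, `d` in
#' `{1, 2}`, a drift term allowed when `d = 1`) by Gaussian maximum
#' likelihood and returns the minimum-AICc specification, with
#' `AICc = -2 loglik + 2 m n / (n - m - 1)` where `m` counts the ARMA
#' coefficients, the drift and the innovation variance and `n` is the
#' series length after differencing.
#'
#' @param x Numeric time series (at least 8 points after differencing).
#' @param d_orders Differencing orders to try.
#' @param max_p,max_q Largest AR and MA orders tried.
#' @param allow_drift Allow a drift term when `d = 1`.
#' @return Object of class `arima_spec`: list with `order = c(p, d, q)`,
#'   `drift` flag, `coef`, `sigma2`, `aicc`, the fitted `stats::arima`
#'   object (`fit`, `NULL` for a degenerate series) and the series `x`.
#' @export
select_arima <- function(x, d_orders = c(1, 2), max_p = 2, max_q = 2,
                         allow_drift = TRUE) {
  x <- as.numeric(x)
  if (length(x) - max(d_orders) < 8) stop("series too short after differencing")
  if (stats::sd(diff(x)) < 1e-12) {
    ## exactly linear (or constant) series: pure drift, no innovation
    warning("differenced series has zero variance; returning a pure-drift specification")
    return(structure(list(order = c(0, 1, 0), drift = TRUE,
                          coef = c(drift = mean(diff(x))), sigma2 = 0,
                          aicc = -Inf, fit = NULL, x = x),
                     class = "arima_spec"))
  }
  best <- NULL
  for (d in d_orders) {
    for (p in 0:max_p) {
      for (q in 0:max_q) {
        for (dr in unique(c(FALSE, allow_drift && d == 1))) {
          cand <- try_arima(x, c(p, d, q), dr)
          if (is.null(cand)) next
          if (is.null(best) || cand$aicc < best$aicc) best <- cand
        }
      }
    }
  }
  if (is.null(best)) stop("no ARIMA candidate could be fitted")
  best
}

## fit one candidate; NULL on failure
try_arima <- function(x, order, drift) {
  n_eff <- length(x) - order[2]
  xreg <- if (drift) matrix(seq_along(x), ncol = 1, dimnames = list(NULL, "drift"))
  fit <- tryCatch(
    suppressWarnings(stats::arima(x, order = order, xreg = xreg,
                                  include.mean = FALSE, method = "ML")),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  ## predict.Arima re-evaluates call$xreg in the caller's frame; store the
  ## literal matrix (or drop the element) so prediction works after this
  ## frame is gone
  fit$call$xreg <- xreg
  m <- sum(order[c(1, 3)]) + as.integer(drift) + 1  # + sigma2
  if (n_eff - m - 1 <= 0) return(NULL)
  aicc <- -2 * fit$loglik + 2 * m * n_eff / (n_eff - m - 1)
  structure(list(order = order, drift = drift, coef = stats::coef(fit),
                 sigma2 = fit$sigma2, aicc = aicc, fit = fit, x = x),
            class = "arima_spec")
}

#' @export
print.arima_spec <- function(x, ...) {
  cat(sprintf("ARIMA(%d,%d,%d)%s, sigma2 = %.4g, AICc = %.4g\n",
              x$order[1], x$order[2], x$order[3],
              if (x$drift) " + drift" else "", x$sigma2, x$aicc))
  invisible(x)
}

#' Refit an ARIMA specification to a new series with fixed orders
#'
#' Used per bootstrap replicate: the Box-Jenkins order selection is done
#' once on the original fit, and only coefficients are re-estimated.
#' Falls back to a random walk with drift when the constrained fit fails.
#'
#' @param x New series.
#' @param spec An `arima_spec` providing the orders and drift flag.
#' @return An `arima_spec` for `x`.
#' @export
refit_arima <- function(x, spec) {
  stopifnot(inherits(spec, "arima_spec"))
  x <- as.numeric(x)
  if (is.null(spec$fit) || stats::sd(diff(x)) < 1e-12) {
    return(structure(list(order = c(0, 1, 0), drift = TRUE,
                          coef = c(drift = mean(diff(x))), sigma2 = 0,
                          aicc = NA_real_, fit = NULL, x = x),
                     class = "arima_spec"))
  }
  out <- try_arima(x, spec$order, spec$drift)
  if (is.null(out)) {
    out <- structure(list(order = c(0, 1, 0), drift = TRUE,
                          coef = c(drift = mean(diff(x))),
                          sigma2 = stats::var(diff(x)), aicc = NA_real_,
                          fit = NULL, x = x),
                     class = "arima_spec")
  }
  out
}

#' Conditional-mean forecast of an index series
#'
#' Point forecasts only; no innovation noise is added, so that bootstrap
#' intervals reflect parameter error alone.  For the pure random walk with
#' drift the closed form `x_T + h * drift` is used.
#'
#' @param spec An `arima_spec` (carrying its series).
#' @param horizon Number of steps ahead.
#' @return Numeric vector of length `horizon`.
#' @export
forecast_index <- function(spec, horizon) {
  stopifnot(inherits(spec, "arima_spec"))
  stopifnot_scalar_count(horizon, "horizon")
  x <- spec$x
  n <- length(x)
  if (is.null(spec$fit)) {              # degenerate / fallback: RW + drift
    dr <- if (spec$drift) unname(spec$coef["drift"]) else 0
    return(x[n] + seq_len(horizon) * dr)
  }
  newxreg <- if (spec$drift)
    matrix(n + seq_len(horizon), ncol = 1, dimnames = list(NULL, "drift"))
  as.numeric(stats::predict(spec$fit, n.ahead = horizon,
                            newxreg = newxreg)$pred)
}

#' Extend a cohort-effect series over the forecast horizon
#'
#' Fits an ARIMA (AICc grid, or the supplied specification's orders) to
#' the estimated (weight-one) cohort effects and forecasts forward to fill
#' the trailing unestimated cohorts and every new cohort entering the
#' grid over the horizon, so each (age, future year) cell has a value.
#' Leading unestimated cohorts are left missing (they are never needed for
#' future years).
#'
#' @param gamma Named per-cohort vector with `NA` for unestimated leading
#'   and trailing cohorts (as returned by [fit_h1()]).
#' @param horizon Number of future years.
#' @param spec Optional `arima_spec` whose orders are reused ([refit_arima()]);
#'   default: selected on the estimated series.
#' @return Named vector over all cohorts from the first observed to
#'   `last cohort + horizon`, with forecasts in place of trailing `NA`s.
#' @export
forecast_gamma <- function(gamma, horizon, spec = NULL) {
  stopifnot_scalar_count(horizon, "horizon")
  est <- which(!is.na(gamma))
  if (length(est) < 8) {
    warning("fewer than 8 estimated cohorts; using a random walk with drift")
    series <- gamma[est]
    dr <- if (length(series) > 1) mean(diff(series)) else 0
    fit <- structure(list(order = c(0, 1, 0), drift = TRUE,
                          coef = c(drift = dr), sigma2 = 0,
                          aicc = NA_real_, fit = NULL,
                          x = as.numeric(series)),
                     class = "arima_spec")
  } else {
    series <- as.numeric(gamma[min(est):max(est)])
    fit <- if (is.null(spec)) select_arima(series) else refit_arima(series, spec)
  }
  n_trail <- length(gamma) - max(est)
  need <- n_trail + horizon
  fc <- forecast_index(fit, need)
  cohorts <- as.integer(names(gamma))
  out <- c(gamma[seq_len(max(est))],
           stats::setNames(fc, max(cohorts) - n_trail + seq_len(need)))
  attr(out, "arima_spec") <- fit
  out
}

#' Project future death probabilities
#'
#' Evaluates `q = inverse-logit(a_x + sum_i b_x^(i) k_t^(i) [+ gamma_{t-x}])`
#' over the forecast years.
#'
#' @param params An `lc_params` fit.
#' @param k_future Matrix of future period-index values, horizon x r.
#' @param future_years Integer vector of forecast years.
#' @param gamma_future Named cohort-effect vector covering every cohort
#'   `year - age` of the forecast grid (cohort model only).
#' @return Ages x future-years matrix of probabilities in `(0, 1)`.
#' @export
project_probabilities <- function(params, k_future, future_years,
                                  gamma_future = NULL) {
  stopifnot(inherits(params, "lc_params"))
  k_future <- as.matrix(k_future)
  H <- length(future_years)
  if (nrow(k_future) != H || ncol(k_future) != ncol(params$K)) {
    stop("k_future must be horizon x r")
  }
  eta <- params$a + params$B %*% t(k_future)
  if (identical(params$family, "H1")) {
    if (is.null(gamma_future)) stop("cohort model needs gamma_future")
    cm <- outer(-params$ages, as.integer(future_years), `+`)
    gg <- matrix(gamma_future[as.character(cm)], nrow = length(params$ages))
    if (anyNA(gg)) stop("incomplete forecast: missing cohort effects for some cells")
    eta <- eta + gg
  }
  q <- stats::plogis(eta)
  dimnames(q) <- list(params$ages, future_years)
  q
}

#' Container for replicate indicator curves over a crossed design
#'
#' @param indicator Indicator name (`"e0"`, `"e65"`, `"modal"`, `"gini"`, ...).
#' @param years Forecast years (length H).
#' @param curves 4-d array `[model, sample, replicate, year]` (factor
#'   levels in the dimnames).
#' @return Object of class `indicator_curve_set`.
#' @export
indicator_curve_set <- function(indicator, years, curves) {
  stopifnot(length(dim(curves)) == 4, dim(curves)[4] == length(years))
  structure(list(indicator = indicator, years = years, curves = curves,
                 N = dim(curves)[3]),
            class = "indicator_curve_set")
}

#' @export
print.indicator_curve_set <- function(x, ...) {
  d <- dim(x$curves)
  cat(sprintf("Indicator '%s': %d x %d design, N = %d replicates, %d years\n",
              x$indicator, d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Mortality indicators of a projected probability surface
#'
#' Builds one period life table per column (future year) of a projected
#' probability matrix and evaluates life expectancy at the requested ages,
#' the modal age at death and the Gini index.
#'
#' @param q Ages x years matrix of death probabilities (ages from 0).
#' @param e_ages Ages at which life expectancy is reported (default 0, 65).
#' @param radix Life-table radix.
#' @return Matrix years x indicators, columns named `e0`, `e65`, ...,
#'   `modal`, `gini`.
#' @export
compute_indicators <- function(q, e_ages = c(0, 65), radix = 1e5) {
  q <- as.matrix(q)
  inds <- c(paste0("e", e_ages), "modal", "gini")
  out <- matrix(NA_real_, ncol(q), length(inds),
                dimnames = list(colnames(q), inds))
  for (j in seq_len(ncol(q))) {
    lt <- build_period_table(q[, j], radix = radix)
    for (i in seq_along(e_ages)) out[j, i] <- life_expectancy(lt, e_ages[i])
    out[j, "modal"] <- modal_age(lt)
    out[j, "gini"] <- suppressWarnings(gini_index(lt))
  }
  out
}

#' Indicator curves for a list of projected replicates
#'
#' @param q_list List of projected probability matrices (one per
#'   replicate, identical shapes).
#' @param e_ages,radix Passed to [compute_indicators()].
#' @return List of replicate indicator matrices (years x indicators).
#' @export
indicator_curves <- function(q_list, e_ages = c(0, 65), radix = 1e5) {
  shapes <- vapply(q_list, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(shapes)) != 1) stop("replicates must share ages and horizon")
  lapply(q_list, compute_indicators, e_ages = e_ages, radix = radix)
}

#' Pointwise percentile confidence bands of replicate curves
#'
#' Empirical quantiles per forecast year across replicates, with the
#' linear-interpolation quantile definition (`stats::quantile` type 7).
#'
#' @param curves N x H matrix (replicates in rows).
#' @param probs Lower and upper probabilities (default 2.5% and 97.5%).
#' @return List with `lower` and `upper` curves of length H.
#' @export
percentile_ci <- function(curves, probs = c(0.025, 0.975)) {
  curves <- as.matrix(curves)
  if (nrow(curves) < 2) {
    warning("fewer than 2 replicates: degenerate interval")
    return(list(lower = curves[1, ], upper = curves[1, ]))
  }
  qs <- apply(curves, 2, stats::quantile, probs = sort(probs), names = FALSE,
              type = 7)
  list(lower = qs[1, ], upper = qs[2, ])
}
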