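# Shared expensive fixtures: one simulated surface and fit per family,
# built once per test run.  Small dimensions keep individual test files
# fast; the acceptance tests use the full-size study conditions.

fix_env <- new.env(parent = emptyenv())

fixture_lc1 <- function() {
  if (is.null(fix_env$lc1)) {
    p <- make_params(A = 30, T = 14, family = "LC1", seed = 42)
    s <- simulate_deaths(p, exposure = 1e6, seed = 43)
    f <- fit_lc(s, r = 1)
    fix_env$lc1 <- list(params = p, surface = s, fit = f)
  }
  fix_env$lc1
}

fixture_h1 <- function() {
  if (is.null(fix_env$h1)) {
    p <- make_params(A = 30, T = 14, family = "H1", seed = 52)
    s <- simulate_deaths(p, exposure = 1e6, seed = 53)
    f <- suppressWarnings(fit_h1(s))
    fix_env$h1 <- list(params = p, surface = s, fit = f)
  }
  fix_env$h1
}

# remove an affine (level + trend in cohort index) difference before
# comparing cohort effects: the standard age-period-cohort near-gauge
gamma_aligned_rmse <- function(gamma_est, gamma_true) {
  est <- !is.na(gamma_est)
  err <- gamma_est[est] - gamma_true[names(gamma_est)][est]
  idx <- seq_along(err)
  sqrt(mean(stats::resid(stats::lm(err ~ idx))^2))
}

# noiseless surface implied by a parameter set (d = E * q exactly)
exact_surface <- function(params, exposure = 1e6) {
  shell <- list(ages = params$ages, years = params$years)
  q <- stats::plogis(mortboot:::eta_from_params(params, shell))
  E <- matrix(exposure, length(params$ages), length(params$years))
  mortality_surface(params$ages, params$years, E, E * q)
}
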