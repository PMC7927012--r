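test_that("order selection identifies a random walk with drift", {
  hits <- 0
  for (sd in 1:50) {
    set.seed(400 + sd)
    x <- cumsum(rnorm(200, mean = -0.8, sd = 0.3))
    sp <- select_arima(x)
    if (all(sp$order == c(0, 1, 0)) && sp$drift) hits <- hits + 1
  }
  expect_gt(hits, 25)                    # majority of seeds
})

test_that("AICc follows the corrected-AIC formula", {
  set.seed(41)
  x <- cumsum(rnorm(60, -0.5, 1))
  cand <- mortboot:::try_arima(x, c(1, 1, 1), drift = TRUE)
  m <- 1 + 1 + 1 + 1                      # ar, ma, drift, sigma2
  n <- length(x) - 1
  expect_equal(cand$aicc, -2 * cand$fit$loglik + 2 * m * n / (n - m - 1),
               tolerance = 1e-10)
})

test_that("an exactly linear series gives a pure-drift spec with the slope", {
  x <- 5 - 0.7 * (1:30)
  expect_warning(sp <- select_arima(x), "zero variance")
  expect_true(sp$drift)
  expect_equal(unname(sp$coef["drift"]), -0.7, tolerance = 1e-12)
  expect_equal(sp$sigma2, 0)
  # forecasts continue the line
  expect_equal(forecast_index(sp, 5), x[30] - 0.7 * (1:5), tolerance = 1e-10)
})

test_that("point forecasts follow the closed forms", {
  # random walk with drift: k_{T+h} = k_T + h c
  set.seed(43)
  x <- cumsum(rnorm(50, -0.8, 0.3))
  sp <- mortboot:::try_arima(x, c(0, 1, 0), drift = TRUE)
  c_hat <- unname(sp$coef["drift"])
  expect_equal(forecast_index(sp, 4), x[50] + (1:4) * c_hat, tolerance = 1e-6)
  # zero-drift random walk: flat forecast
  sp0 <- mortboot:::try_arima(x, c(0, 1, 0), drift = FALSE)
  expect_equal(forecast_index(sp0, 3), rep(x[50], 3), tolerance = 1e-10)
  # stationary AR(1): geometric decay towards zero (no mean term)
  set.seed(44)
  y <- as.numeric(arima.sim(list(ar = 0.6), n = 300))
  spa <- mortboot:::try_arima(y, c(1, 0, 0), drift = FALSE)
  phi <- unname(spa$coef["ar1"])
  fc <- forecast_index(spa, 5)
  expect_equal(fc, y[300] * phi^(1:5), tolerance = 1e-6)
})

test_that("refitting keeps orders fixed and falls back gracefully", {
  set.seed(45)
  x <- cumsum(rnorm(40, -0.5, 0.4))
  sp <- select_arima(x)
  y <- cumsum(rnorm(40, -0.5, 0.4))
  sp2 <- refit_arima(y, sp)
  expect_equal(sp2$order, sp$order)
  expect_equal(sp2$drift, sp$drift)
  # linear new series: fallback to closed-form drift
  sp3 <- refit_arima(1:40, sp)
  expect_equal(unname(sp3$coef["drift"]), 1, tolerance = 1e-12)
})

test_that("cohort extension fills trailing and future cohorts exactly", {
  # gamma over cohorts 1900..1949, 5 leading + 5 trailing unestimated
  cohorts <- 1900:1949
  gamma <- setNames(rep(NA_real_, 50), cohorts)
  gamma[6:45] <- 0.3 * sin(2 * pi * (6:45) / 40)
  ext <- suppressWarnings(forecast_gamma(gamma, horizon = 20))
  new_cohorts <- as.integer(names(ext)[is.na(gamma[names(ext)]) |
                                         !names(ext) %in% names(gamma)])
  expect_equal(length(ext), 45 + 25)      # estimated head + 5 trailing + 20 new
  expect_equal(as.integer(utils::tail(names(ext), 1)), 1969)
  expect_true(all(!is.na(utils::tail(ext, 25))))
  # linear gamma extends the line; constant gamma stays constant
  glin <- setNames(0.01 * (1:30), 2001:2030)
  extl <- suppressWarnings(forecast_gamma(glin, horizon = 10))
  expect_equal(unname(utils::tail(extl, 10)), 0.01 * (31:40), tolerance = 1e-8)
  gcon <- setNames(rep(0.2, 30), 2001:2030)
  extc <- suppressWarnings(forecast_gamma(gcon, horizon = 10))
  expect_equal(unname(utils::tail(extc, 10)), rep(0.2, 10), tolerance = 1e-8)
})

test_that("probability projection evaluates the predictor and stays in (0,1)", {
  p <- mortboot:::new_lc_params("LC1", 0:2, 2001:2003, a = c(-4, -4, -4),
                                B = matrix(c(0.02, 0.48, 0.5), 3),
                                K = matrix(c(0, -5, -10), 3), t0 = 2001)
  kf <- matrix(c(-15, -20), 2)
  qf <- project_probabilities(p, kf, 2004:2005)
  expect_equal(qf[1, 1], plogis(-4 + 0.02 * -15), tolerance = 1e-12)
  expect_true(all(qf > 0 & qf < 1))
  # declining index with positive loadings: probabilities fall every age
  expect_true(all(qf[, 2] < qf[, 1]))
  # cohort model demands complete gamma coverage
  ph <- p; ph$family <- "H1"
  expect_error(project_probabilities(ph, kf, 2004:2005), "gamma_future")
  gf <- setNames(rep(0.1, 3), 2002:2004)  # cohorts 2004-2, ..., 2005-0 missing
  expect_error(project_probabilities(ph, kf, 2004:2005, gamma_future = gf),
               "incomplete")
})

test_that("indicator curves equal a replicate-wise recomputation", {
  p <- make_params(A = 70, T = 12, family = "LC1", seed = 61)
  shell <- list(ages = p$ages, years = p$years)
  q1 <- plogis(mortboot:::eta_from_params(p, shell))[, 1:5]
  q2 <- q1 * 0.9
  curves <- indicator_curves(list(q1, q2), e_ages = c(0, 65))
  expect_length(curves, 2)
  # independent re-evaluation through the public life-table API
  for (j in 1:5) {
    lt <- build_period_table(q1[, j])
    expect_equal(unname(curves[[1]][j, "e0"]), life_expectancy(lt, 0))
    expect_equal(unname(curves[[1]][j, "e65"]), life_expectancy(lt, 65))
    expect_equal(unname(curves[[1]][j, "modal"]), modal_age(lt))
    expect_equal(unname(curves[[1]][j, "gini"]), gini_index(lt))
  }
  expect_error(indicator_curves(list(q1, q1[, 1:3])), "share ages")
})

test_that("improving mortality gives a non-decreasing life-expectancy curve", {
  p <- make_params(A = 70, T = 12, family = "LC1", seed = 62)
  kf <- matrix(seq(-2, -20, length.out = 10))
  qf <- project_probabilities(p, kf, 2003:2012)
  ind <- compute_indicators(qf, e_ages = 0)
  expect_true(all(diff(ind[, "e0"]) >= 0))
})

test_that("percentile bands follow the interpolation quantile rule", {
  curves <- matrix(1:40, nrow = 40, ncol = 3)
  ci <- percentile_ci(curves)
  expect_equal(ci$lower, rep(quantile(1:40, 0.025, names = FALSE), 3))
  expect_equal(ci$upper, rep(quantile(1:40, 0.975, names = FALSE), 3))
  # hand value of the type-7 rule at p = 0.025 on 1..40: 1 + 0.975
  expect_equal(ci$lower[1], 1.975)
  # identical replicates: zero width; interval contains the median
  same <- matrix(5, 4, 3)
  ci0 <- percentile_ci(same)
  expect_equal(ci0$lower, ci0$upper)
  set.seed(63)
  rc <- matrix(rnorm(200), 20, 10)
  cir <- percentile_ci(rc)
  med <- apply(rc, 2, median)
  expect_true(all(cir$lower <= med & med <= cir$upper))
  expect_warning(percentile_ci(matrix(1, 1, 3)), "degenerate")
})
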