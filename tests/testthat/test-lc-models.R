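test_that("logit clipping round-trips and handles boundaries", {
  q <- matrix(c(0.5, 0.1, 0.9, 0.0001), 2)
  expect_equal(inv_logit(logit_clip(q)), q, tolerance = 1e-12)
  expect_equal(logit_clip(0.5), 0)
  expect_equal(logit_clip(0, eps = 1e-8), log(1e-8 / (1 - 1e-8)))
  expect_error(logit_clip(1.2), "\\[0, 1\\]")
})

test_that("SVD initialization reproduces an exactly bilinear surface", {
  p <- make_params(A = 20, T = 12, family = "LC1", seed = 1)
  s <- exact_surface(p)
  init <- init_svd(s, r = 1)
  eta_true <- p$a + p$B %*% t(p$K)
  eta_init <- init$a + init$B %*% t(init$K)
  expect_lt(max(abs(eta_true - eta_init)), 1e-6)
  # constraints hold at initialization
  expect_equal(init$K[1, 1], 0, tolerance = 1e-12)
  expect_equal(sum(init$B[, 1]), 1, tolerance = 1e-12)
})

test_that("rank-2 initial period indices are centered and orthogonal", {
  p <- make_params(A = 25, T = 14, family = "LC2", seed = 2)
  s <- simulate_deaths(p, exposure = 1e6, seed = 3)
  init <- init_svd(s, r = 2)
  K <- scale(init$K, center = TRUE, scale = FALSE)
  expect_lt(abs(sum(K[, 1] * K[, 2])) / sqrt(sum(K[, 1]^2) * sum(K[, 2]^2)),
            1e-10)
})

test_that("initial loadings track truth on high-exposure simulations", {
  p <- make_params(A = 40, T = 15, family = "LC1", seed = 4)
  s <- simulate_deaths(p, exposure = 1e8, seed = 5)
  init <- init_svd(s, r = 1)
  b <- init$B[, 1] * sign(sum(init$B[, 1]))
  expect_gt(cor(b, p$B[, 1]), 0.99)
})

test_that("degenerate constant surface yields a zero index with a warning", {
  E <- matrix(1e5, 10, 10)
  d <- matrix(1e3, 10, 10)
  s <- mortality_surface(0:9, 2001:2010, E, d)
  expect_warning(init <- init_svd(s, r = 1), "rank-deficient")
  expect_true(all(init$K == 0))
})

test_that("fit interpolates a noiseless generated surface", {
  p <- make_params(A = 25, T = 12, family = "LC1", seed = 6)
  s <- exact_surface(p)
  f <- fit_lc(s, r = 1)
  expect_lt(model_deviance(s, f)$deviance, 1e-6)
  # recovered parameters equal truth in the shared gauge
  expect_equal(f$B[, 1], p$B[, 1], tolerance = 1e-6)
  expect_equal(f$K[, 1], p$K[, 1], tolerance = 1e-5)
})

test_that("fitted parameters satisfy the reporting constraints exactly", {
  for (fam in c("LC1", "LC2")) {
    f <- if (fam == "LC1") fixture_lc1()$fit else {
      p <- make_params(A = 25, T = 12, family = "LC2", seed = 7)
      fit_lc(simulate_deaths(p, exposure = 1e6, seed = 8), r = 2)
    }
    for (i in seq_len(ncol(f$K))) {
      expect_equal(f$K[match(f$t0, f$years), i], 0, tolerance = 1e-12)
      expect_equal(sum(f$B[, i]), 1, tolerance = 1e-12)
    }
  }
})

test_that("parameter recovery approaches truth as exposure grows", {
  fx <- fixture_lc1()
  expect_gt(cor(fx$fit$B[, 1], fx$params$B[, 1]), 0.95)
  p <- fx$params
  s8 <- simulate_deaths(p, exposure = 1e8, seed = 44)
  f8 <- fit_lc(s8, r = 1)
  expect_gt(cor(f8$B[, 1], p$B[, 1]), 0.999)
  expect_lt(sqrt(mean((f8$K[, 1] - p$K[, 1])^2)), 0.05)
})

test_that("gauge fixing leaves fitted probabilities and deviance unchanged", {
  fx <- fixture_lc1()
  s <- fx$surface
  f <- fx$fit
  # apply an arbitrary invertible gauge change and undo via gauge fixing
  alpha <- 2.5; beta <- -1.3
  g <- f
  g$B[, 1] <- f$B[, 1] / alpha
  g$K[, 1] <- alpha * f$K[, 1] + beta
  g$a <- f$a - f$B[, 1] * beta / alpha
  expect_equal(model_deviance(s, g)$deviance, model_deviance(s, f)$deviance,
               tolerance = 1e-9)
  gf <- mortboot:::gauge_fix_lc(g$a, g$B, g$K, match(f$t0, f$years))
  expect_equal(gf$a, f$a, tolerance = 1e-8)
  expect_equal(gf$B, f$B, tolerance = 1e-8)
  expect_equal(gf$K, f$K, tolerance = 1e-8)
})

test_that("fit is invariant under relabeling of calendar years", {
  fx <- fixture_lc1()
  s <- fx$surface
  s2 <- mortality_surface(s$ages, s$years + 500, s$E, s$d)
  f1 <- fx$fit
  f2 <- fit_lc(s2, r = 1)
  expect_equal(fitted_deaths(f2, s2), fitted_deaths(f1, s),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("second component stays negligible on a one-component surface", {
  # the spurious component absorbs only sampling noise, so its
  # contribution to the fitted logits vanishes as exposure grows
  p <- make_params(A = 30, T = 14, family = "LC1", seed = 9)
  sup2 <- vapply(c(1e6, 1e8), function(E) {
    f2 <- fit_lc(simulate_deaths(p, exposure = E, seed = 10), r = 2)
    max(abs(f2$B[, 2] %*% t(f2$K[, 2])))
  }, numeric(1))
  expect_lt(sup2[2], 0.05)
  expect_lt(sup2[2], sup2[1] / 3)
  f2 <- fit_lc(simulate_deaths(p, exposure = 1e8, seed = 10), r = 2)
  expect_gt(cor(f2$B[, 1], p$B[, 1]), 0.99)
})

test_that("deviance decreases monotonically over sweeps", {
  p <- make_params(A = 25, T = 12, family = "LC1", seed = 11)
  s <- simulate_deaths(p, exposure = 1e5, seed = 12)
  init <- init_svd(s, r = 1)
  core <- mortboot:::fit_core(s, "LC1", 1L, s$years[1], 1e-8, 50, 1e-8, init)
  expect_true(all(diff(core$trace) <= 1e-9 * pmax(core$trace[-length(core$trace)], 1)))
})

test_that("parameter counts follow the goodness-of-fit table convention", {
  expect_equal(param_count("LC1", 100, 22)$total, 100 + 22 + 100)
  expect_equal(param_count("LC2", 100, 22)$total, 100 + 2 * 22 + 2 * 100)
  expect_equal(param_count("H1", 100, 22)$cohort, 121)
  expect_equal(param_count("H1", 100, 22)$total, 100 + 22 + 100 + 121)
})

test_that("fitted deaths evaluate the predictor directly and stay bounded", {
  # single-cell style hand check via a 3x3 surface with constant parameters
  E <- matrix(10, 3, 3)
  s <- mortality_surface(0:2, 2001:2003, E, matrix(1, 3, 3))
  f <- mortboot:::new_lc_params("LC1", 0:2, 2001:2003,
                                a = rep(-4, 3), B = matrix(1 / 3, 3),
                                K = matrix(c(0, 2, 2), 3), t0 = 2001)
  dh <- fitted_deaths(f, s)
  expect_equal(dh[1, 2], 10 * plogis(-4 + 2 / 3), tolerance = 1e-12)
  expect_equal(unname(dh[, 1]), rep(10 * plogis(-4), 3), tolerance = 1e-12)
  expect_true(all(dh >= 0 & dh <= E))
  # zero index: fitted counts broadcast the intercept over years
  f$K[] <- 0
  dh0 <- fitted_deaths(f, s)
  expect_true(all(abs(dh0 - 10 * plogis(-4)) < 1e-12))
})

test_that("surfaces with an all-zero exposure row are rejected", {
  E <- matrix(1e4, 10, 10); E[3, ] <- 0
  d <- matrix(10, 10, 10); d[3, ] <- 0
  s <- mortality_surface(0:9, 2001:2010, E, d)
  expect_error(fit_lc(s, r = 1), "zero exposure")
})

test_that("two-stage cohort fit honors weights, positivity and constraints", {
  fx <- fixture_h1()
  f <- fx$fit
  expect_equal(sum(is.na(f$gamma)), 10)          # 5 leading + 5 trailing
  expect_true(all(is.na(f$gamma[1:5])))
  expect_true(all(is.na(f$gamma[length(f$gamma) - 0:4])))
  expect_true(all(f$B > 0))
  expect_equal(sum(f$B), 1, tolerance = 1e-12)
  expect_equal(f$K[1, 1], 0, tolerance = 1e-12)
  # stage 1: intercepts are the year-means of the observed logits
  expect_equal(f$a, unname(rowMeans(logit_clip(fx$surface$q))), tolerance = 1e-12)
})

test_that("cohort effects are recovered up to the affine cohort near-gauge", {
  p <- make_params(A = 90, T = 20, family = "H1", seed = 5)
  s <- simulate_deaths(p, exposure = 1e6, seed = 6)
  f <- suppressWarnings(fit_h1(s))
  expect_lt(gamma_aligned_rmse(f$gamma, p$gamma), 0.1)
})

test_that("model deviance equals the sum of squared deviance residuals", {
  fx <- fixture_lc1()
  dh <- fitted_deaths(fx$fit, fx$surface)
  r <- deviance_residuals(fx$surface$d, dh, fx$surface$E)
  expect_equal(sum(r$r[r$mask]^2), model_deviance(fx$surface, fx$fit)$deviance,
               tolerance = 1e-8)
  expect_error(model_deviance(simulate_deaths(make_params(12, 12, seed = 1), 100, seed = 1),
                              fx$fit),
               "shapes differ")
})
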