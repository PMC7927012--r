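## Synthetic mortality surfaces with known Lee-Carter / cohort structure.
## The generator emulates the study conditions of a national male
## population: an age profile with infant mortality and a Gompertz-like
## rise, positive age loadings concentrated at young ages, a period index
## following a random walk with drift, an optional small second component
## and a smooth bounded cohort effect, with binomial (or beta-binomial
## overdispersed) death counts.

#' Ground-truth parameters for a synthetic mortality surface
#'
#' The stylized age schedule is
#' `q*_x = c1 exp(-c2 x) + c3 exp(c4 x)` capped at 0.7
#' (infant decline plus Gompertz rise), the loadings are proportional to
#' `1/(x + 5)` normalized to sum one, and the period index is a realized
#' random walk with drift, shifted to zero at the first year.  The
#' two-term family adds a second component with a smooth age bump and a
#' small stationary AR(1) index; the cohort family adds a bounded
#' sinusoidal cohort effect.
#'
#' @param A,T Number of ages (from age 0) and of calendar years.
#' @param family `"LC1"`, `"LC2"` or `"H1"`.
#' @param seed Integer seed (all generators are deterministic given it).
#' @param drift,sigma_k Drift and innovation standard deviation of the
#'   period random walk, in logit units per year (defaults -0.8 and 0.3
#'   on the summed-loading scale, i.e. multiplied by `b_x` per age).
#' @param schedule Coefficients `(c1, c2, c3, c4)` of the age schedule.
#' @param gamma_amp Amplitude of the sinusoidal cohort effect (logit units).
#' @param first_year First calendar year (default 1991).
#' @return An `lc_params` object carrying the ground truth (for `"H1"`,
#'   `gamma` is fully known and all cohort weights are 1).
#' @export
make_params <- function(A = 90, T = 20, family = c("LC1", "LC2", "H1"),
                        seed = 1, drift = -0.8, sigma_k = 0.3,
                        schedule = c(0.004, 0.6, 5e-5, 0.085),
                        gamma_amp = 0.2, first_year = 1991L) {
  family <- match.arg(family)
  if (A < 10 || T < 10) stop("need at least 10 ages and 10 years")
  set.seed(derive_seed(seed, 101))
  ages <- 0:(A - 1L)
  years <- seq.int(first_year, length.out = T)
  qstar <- pmin(schedule[1] * exp(-schedule[2] * ages) +
                  schedule[3] * exp(schedule[4] * ages), 0.7)
  a <- as.vector(logit_clip(qstar))
  b <- 1 / (ages + 5); b <- b / sum(b)
  k <- cumsum(stats::rnorm(T, mean = drift, sd = sigma_k))
  k <- k - k[1]
  B <- matrix(b); K <- matrix(k)
  if (family == "LC2") {
    b2 <- exp(-((ages - 30) / 15)^2)
    b2 <- b2 / sum(b2)
    k2 <- as.vector(stats::arima.sim(list(ar = 0.5), n = T, sd = 1.0))
    k2 <- k2 - k2[1]
    B <- unname(cbind(B, b2)); K <- unname(cbind(K, k2))
  }
  gamma <- NULL; cw <- NULL
  if (family == "H1") {
    cohorts <- seq.int(years[1] - ages[A], years[T] - ages[1])
    gamma <- gamma_amp * sin(2 * pi * seq_along(cohorts) / 40)
    names(gamma) <- cohorts
    cw <- rep(1L, length(cohorts)); names(cw) <- cohorts
  }
  new_lc_params(family, ages, years, a, B, K, t0 = years[1],
                gamma = gamma, cohort_weights = cw,
                dispersion = 1, deviance = 0, converged = TRUE,
                iterations = 0L)
}

#' Simulate death counts for a parameter set
#'
#' Draws binomial counts `d ~ Binomial(E, q)` with
#' `q = inverse-logit(predictor)`; with `dispersion > 1` a beta-binomial
#' with the same mean and variance `dispersion * E q (1 - q)` is used
#' (mixing probability `Beta` with intra-class correlation
#' `(dispersion - 1) / (E - 1)`).
#'
#' @param params An `lc_params` ground truth (e.g. from [make_params()]).
#' @param exposure Exposure per cell: scalar or per-age vector (persons).
#' @param dispersion Variance-inflation factor `phi >= 1`.
#' @param seed Integer seed.
#' @return A `mortality_surface`.
#' @export
simulate_deaths <- function(params, exposure = 1e5, dispersion = 1,
                            seed = 1) {
  stopifnot(inherits(params, "lc_params"))
  if (dispersion < 1) stop("dispersion must be >= 1")
  if (any(exposure <= 0)) stop("exposures must be positive")
  A <- length(params$ages); T <- length(params$years)
  E <- matrix(round(exposure), A, T)
  shell <- list(ages = params$ages, years = params$years)
  q <- stats::plogis(eta_from_params(params, shell))
  set.seed(derive_seed(seed, 202))
  if (dispersion == 1) {
    d <- matrix(stats::rbinom(A * T, E, q), A, T)
  } else {
    rho <- (dispersion - 1) / pmax(E - 1, 1)
    al <- q * (1 - rho) / rho
    be <- (1 - q) * (1 - rho) / rho
    p <- matrix(stats::rbeta(A * T, al, be), A, T)
    d <- matrix(stats::rbinom(A * T, E, p), A, T)
  }
  mortality_surface(params$ages, params$years, E, d)
}

#' Balanced functional-ANOVA fixture with known effect functions
#'
#' Generates `3 x 3 x N` curves on an `H`-point grid from the two-way
#' functional decomposition
#' `X = m(t) + f_mod(t) + g_sam(t) + h_mod,sam(t) + noise`, with smooth
#' effect shapes scaled by the requested sizes and iid Gaussian noise at
#' every grid point.  Zero effect sizes give exchangeable cells (a true
#' null).  Effect functions satisfy the usual sum-to-zero identification
#' across levels.
#'
#' @param effect_model,effect_sample,effect_interaction Peak amplitudes of
#'   the three effect functions, in the same units as `noise_sd`.
#' @param N Replicates per cell.
#' @param H Grid points per curve.
#' @param noise_sd Standard deviation of the pointwise Gaussian noise.
#' @param seed Integer seed.
#' @return An `indicator_curve_set` with `indicator = "fixture"`, cells
#'   labelled by factor levels `M1..M3` and `S1..S3`.
#' @export
make_fanova_fixture <- function(effect_model = 0, effect_sample = 0,
                                effect_interaction = 0, N = 10, H = 20,
                                noise_sd = 1, seed = 1) {
  if (N < 2 || H < 2) stop("need N >= 2 and H >= 2")
  set.seed(derive_seed(seed, 303))
  tg <- seq(0, 1, length.out = H)
  m <- 10 + 2 * sin(pi * tg)
  shape_f <- sin(pi * tg)
  shape_g <- cos(pi * tg)
  shape_h <- sin(2 * pi * tg)
  u <- c(1, -0.5, -0.5)                 # sum-to-zero level contrasts
  curves <- array(NA_real_, dim = c(3, 3, N, H),
                  dimnames = list(model = paste0("M", 1:3),
                                  sample = paste0("S", 1:3),
                                  rep = NULL, t = NULL))
  for (i in 1:3) {
    for (j in 1:3) {
      mean_ij <- m + effect_model * u[i] * shape_f +
        effect_sample * u[j] * shape_g +
        effect_interaction * u[i] * u[j] * shape_h
      noise <- matrix(stats::rnorm(N * H, sd = noise_sd), N, H)
      curves[i, j, , ] <- sweep(noise, 2, mean_ij, `+`)
    }
  }
  indicator_curve_set("fixture", seq_len(H), curves)
}
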