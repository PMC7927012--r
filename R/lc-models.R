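## Lee-Carter-family models on the logit of the death probability, fitted
## by quasi-binomial maximum likelihood:
##   LC1 / LC2:  logit q_xt = a_x + sum_i b_x^(i) k_t^(i),  i <= r in {1,2}
##   H1:         logit q_xt = a_x + b_x k_t + gamma_{t-x},  a_x fixed in
##               stage 1 as the year-mean of the observed logits.
## Point estimates are binomial ML (the quasi-binomial dispersion phi only
## rescales variances); estimation is alternating damped Newton updates on
## the per-age, per-year and per-cohort blocks, which are conditionally
## independent given the other blocks.

CLIP_EPS <- 1e-8

## cellwise binomial deviance contribution 2*[d log(d/dhat) + (E-d) log((E-d)/(E-dhat))]
## with the 0*log 0 = 0 convention
binom_dev_cells <- function(d, dhat, E) {
  t1 <- ifelse(d > 0, d * log(d / dhat), 0)
  t2 <- ifelse(E - d > 0, (E - d) * log((E - d) / (E - dhat)), 0)
  2 * (t1 + t2)
}

## number of estimated parameters, by the counting convention of the
## goodness-of-fit table (constraints are not subtracted)
#' Parameter count of a Lee-Carter-family model
#'
#' Counting convention: `A + T + A` for the one-term model, `A + 2T + 2A`
#' with two terms, and `A + T + A + (T + A - 1)` for the cohort model,
#' where A is the number of ages and T the number of years.  Identifying
#' constraints are not subtracted.
#'
#' @param family `"LC1"`, `"LC2"` or `"H1"`.
#' @param A,T Number of ages and of calendar years.
#' @return List with `total` and the per-block counts `a`, `bk`, `cohort`.
#' @export
param_count <- function(family, A, T) {
  family <- match.arg(family, c("LC1", "LC2", "H1"))
  r <- if (family == "LC2") 2L else 1L
  cohort <- if (family == "H1") T + A - 1L else 0L
  list(total = A + r * (A + T) + cohort, a = A, bk = r * (A + T),
       cohort = cohort)
}

## cohort weights: zero for the first five and last five cohorts
cohort_weights_for <- function(surface, n_edge = 5L) {
  cohorts <- cohort_range(surface)
  w <- rep(1L, length(cohorts))
  w[seq_len(min(n_edge, length(w)))] <- 0L
  w[seq.int(length(w) - min(n_edge, length(w)) + 1L, length(w))] <- 0L
  names(w) <- cohorts
  w
}

## gamma values mapped onto the surface grid (NA where gamma is missing)
gamma_grid <- function(gamma, surface) {
  cm <- cohort_matrix(surface)
  matrix(gamma[as.character(cm)], nrow = nrow(cm))
}

## linear predictor on the logit scale
eta_from_params <- function(params, surface, gamma_fill = 0) {
  eta <- params$a + params$B %*% t(params$K)
  if (identical(params$family, "H1")) {
    gg <- gamma_grid(params$gamma, surface)
    gg[is.na(gg)] <- gamma_fill
    eta <- eta + gg
  }
  eta
}

new_lc_params <- function(family, ages, years, a, B, K, t0,
                          gamma = NULL, cohort_weights = NULL,
                          dispersion = NA_real_, deviance = NA_real_,
                          converged = NA, iterations = NA_integer_) {
  structure(
    list(family = family, ages = ages, years = years, a = as.vector(a),
         B = as.matrix(B), K = as.matrix(K), t0 = t0, gamma = gamma,
         cohort_weights = cohort_weights, dispersion = dispersion,
         deviance = deviance, converged = converged,
         iterations = iterations),
    class = "lc_params"
  )
}

#' @export
print.lc_params <- function(x, ...) {
  cat(sprintf("%s fit: %d ages x %d years, deviance %.4g, dispersion %.3g\n",
              x$family, length(x$ages), length(x$years), x$deviance,
              x$dispersion))
  invisible(x)
}

#' Singular-value-decomposition starting values
#'
#' Clips the crude probabilities, takes logits, sets the age intercept to
#' the per-age mean and extracts the leading `r` singular triplets of the
#' row-centered logit matrix, rescaled to the reporting constraints
#' (loadings summing to one, period index zero at the reference year).
#'
#' @param surface A `mortality_surface`.
#' @param r Number of bilinear terms (1 or 2).
#' @param t0 Reference year for the location constraint (default: first).
#' @param eps Probability clipping bound.
#' @return An `lc_params` object (family `"LC1"` or `"LC2"`).
#' @export
init_svd <- function(surface, r = 1, t0 = NULL, eps = CLIP_EPS) {
  A <- length(surface$ages); T <- length(surface$years)
  if (A < 3 || T < 3) stop("need at least a 3x3 surface")
  if (!r %in% 1:2) stop("r must be 1 or 2")
  t0 <- t0 %||% surface$years[1]
  t0i <- match(t0, surface$years)
  L <- logit_clip(ifelse(is.na(surface$q), 0.5, surface$q), eps)
  a <- rowMeans(L)
  sv <- svd(L - a, nu = r, nv = r)
  B <- matrix(0, A, r); K <- matrix(0, T, r)
  if (sv$d[1] < 1e-10) {
    warning("surface is rank-deficient (constant logits); period index set to 0")
    B[] <- 1 / A
  } else {
    for (i in seq_len(r)) {
      u <- sv$u[, i]; s <- sum(u)
      if (abs(s) < 1e-8) s <- sign(s + 1e-30) * 1e-8
      B[, i] <- u / s
      K[, i] <- sv$d[i] * sv$v[, i] * s
    }
    a <- a + as.vector(B %*% K[t0i, ])
    K <- sweep(K, 2, K[t0i, ])
  }
  new_lc_params(if (r == 2) "LC2" else "LC1", surface$ages, surface$years,
                a, B, K, t0)
}

## ---- alternating damped Newton core --------------------------------------

## one damped update: accept candidate parameter list if deviance does not
## increase, halving the step up to 30 times
damp_accept <- function(dev_fun, cur, cand_fun) {
  dev0 <- dev_fun(cur)
  s <- 1
  for (h in 1:30) {
    cand <- cand_fun(cur, s)
    dev1 <- dev_fun(cand)
    if (is.finite(dev1) && dev1 <= dev0 + 1e-12 * max(1, dev0)) {
      return(list(par = cand, dev = dev1))
    }
    s <- s / 2
  }
  list(par = cur, dev = dev0)
}

## solve small ridge-stabilized normal equations
solve_newton <- function(H, g) {
  dg <- diag(H)
  ridge <- 1e-10 * max(dg, 1e-30)
  solve(H + diag(ridge, nrow(H)), g)
}

fit_core <- function(surface, family, r, t0, eps, max_sweeps, tol, init,
                     verbose = FALSE) {
  A <- length(surface$ages); T <- length(surface$years)
  E <- surface$E; d <- surface$d
  if (any(rowSums(E) == 0) || any(colSums(E) == 0)) {
    stop("unidentifiable cells: an entire age row or year column has zero exposure")
  }
  t0i <- match(t0, surface$years)
  h1 <- identical(family, "H1")

  cohort_w <- NULL; cidx <- NULL; ncoh <- 0L
  mask <- E > 0
  if (h1) {
    cohort_w <- cohort_weights_for(surface)
    cm <- cohort_matrix(surface)
    cidx <- matrix(match(cm, as.integer(names(cohort_w))), nrow = A)
    ncoh <- length(cohort_w)
    mask <- mask & matrix(cohort_w[cidx] == 1L, nrow = A)
    if (!any(mask)) stop("no cohort carries weight 1")
  }
  wmask <- ifelse(mask, 1, 0)

  gamma0 <- NULL
  if (h1) {
    gamma0 <- init$gamma %||% rep(0, ncoh)
    if (all(gamma0 == 0)) {
      ## start gamma at the cohort-diagonal means of the residual logits:
      ## the coupling between the cohort diagonals and the bilinear term
      ## makes backfitting from gamma = 0 very slow
      L <- logit_clip(ifelse(is.na(surface$q), 0.5, surface$q), eps)
      R <- (L - init$a - init$B %*% t(init$K))
      R[!mask] <- NA
      mg <- tapply(as.vector(R), as.vector(cidx), mean, na.rm = TRUE)
      gamma0[as.integer(names(mg))] <- ifelse(is.finite(mg), mg, 0)
    }
  }
  par <- list(a = init$a, B = as.matrix(init$B), K = as.matrix(init$K),
              gamma = gamma0)

  eta_of <- function(p) {
    eta <- p$a + p$B %*% t(p$K)
    if (h1) eta <- eta + matrix(p$gamma[cidx], nrow = A)
    eta
  }
  dev_of <- function(p) {
    mu <- stats::plogis(eta_of(p))
    sum(binom_dev_cells(d, E * mu, E)[mask])
  }

  dev <- dev_of(par)
  trace <- dev
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_sweeps)) {
    dev_prev <- dev
    par_prev <- par

    ## --- per-age block: (a_x, b_x) for LC, b_x only for H1 (a fixed) ----
    mu <- stats::plogis(eta_of(par))
    w <- E * mu * (1 - mu) * wmask
    res <- (d - E * mu) * wmask
    if (h1) {
      k <- par$K[, 1]
      num <- as.vector(res %*% k)
      den <- as.vector(w %*% (k * k))
      db <- ifelse(den > 0, num / den, 0)
      st <- damp_accept(dev_of, par, function(p, s) {
        p$B[, 1] <- p$B[, 1] + s * db
        p
      })
    } else {
      X <- cbind(1, par$K)                      # T x (r+1), same for all ages
      delta <- matrix(0, A, r + 1)
      for (x in seq_len(A)) {
        Wx <- w[x, ]
        H <- crossprod(X * Wx, X)
        g <- crossprod(X, res[x, ])
        delta[x, ] <- solve_newton(H, g)
      }
      st <- damp_accept(dev_of, par, function(p, s) {
        p$a <- p$a + s * delta[, 1]
        p$B <- p$B + s * delta[, -1, drop = FALSE]
        p
      })
    }
    par <- st$par; dev <- st$dev

    ## --- per-year block: k_t (k at t0 pinned to 0 for H1) ---------------
    mu <- stats::plogis(eta_of(par))
    w <- E * mu * (1 - mu) * wmask
    res <- (d - E * mu) * wmask
    Bm <- par$B                                 # A x r
    dk <- matrix(0, T, r)
    for (t in seq_len(T)) {
      if (h1 && t == t0i) next
      H <- crossprod(Bm * w[, t], Bm)
      g <- crossprod(Bm, res[, t])
      dk[t, ] <- solve_newton(H, g)
    }
    st <- damp_accept(dev_of, par, function(p, s) {
      p$K <- p$K + s * dk
      p
    })
    par <- st$par; dev <- st$dev

    ## --- per-cohort block (H1 only) -------------------------------------
    if (h1) {
      mu <- stats::plogis(eta_of(par))
      num <- rowsum(as.vector((d - E * mu) * wmask), as.vector(cidx))
      den <- rowsum(as.vector(E * mu * (1 - mu) * wmask), as.vector(cidx))
      dg <- rep(0, ncoh)
      dg[as.integer(rownames(num))] <- ifelse(den > 0, num / den, 0)
      st <- damp_accept(dev_of, par, function(p, s) {
        p$gamma <- p$gamma + s * dg
        p
      })
      par <- st$par; dev <- st$dev

      ## enforce b > 0 (clip) and the scale constraint sum(b) = 1; the
      ## rescale is pure gauge (k absorbs it), the clip is a projection
      b <- pmax(par$B[, 1], 1e-6)
      sb <- sum(b)
      par$B[, 1] <- b / sb
      par$K[, 1] <- par$K[, 1] * sb
      dev <- dev_of(par)
    } else if (r == 2) {
      ## re-orthogonalize the bilinear term mid-fit (pure gauge) to keep
      ## the per-age 3x3 systems well conditioned
      M <- par$B %*% t(par$K)
      sv <- svd(M, nu = 2, nv = 2)
      par$B <- sv$u
      par$K <- sv$v %*% diag(sv$d[1:2], 2)
      dev <- dev_of(par)
    }

    ## over-relaxation: extrapolate along the sweep direction to cross the
    ## nearly flat valley that couples the cohort trend with the bilinear
    ## term (plain backfitting crawls along it)
    if (dev < dev_prev) {
      for (s in c(16, 8, 4, 2)) {
        cand <- par
        cand$a <- par_prev$a + (1 + s) * (par$a - par_prev$a)
        cand$B <- par_prev$B + (1 + s) * (par$B - par_prev$B)
        cand$K <- par_prev$K + (1 + s) * (par$K - par_prev$K)
        if (h1) {
          cand$gamma <- par_prev$gamma + (1 + s) * (par$gamma - par_prev$gamma)
          b <- pmax(cand$B[, 1], 1e-6); sb <- sum(b)
          cand$B[, 1] <- b / sb
          cand$K[, 1] <- cand$K[, 1] * sb
        }
        dev_c <- dev_of(cand)
        if (is.finite(dev_c) && dev_c < dev) {
          par <- cand
          dev <- dev_c
          break
        }
      }
    }

    trace <- c(trace, dev)
    if (abs(dev_prev - dev) <= tol * max(dev_prev, 1e-10)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("fit did not converge in %d sweeps (last deviances: %s)",
                    max_sweeps,
                    paste(signif(utils::tail(trace, 3), 8), collapse = ", ")))
  }
  if (verbose) message(sprintf("%s: %d sweeps, deviance %.6g", family, it, dev))
  list(par = par, deviance = dev, mask = mask, cidx = cidx,
       cohort_w = cohort_w, converged = converged, iterations = it,
       trace = trace)
}

## post-fit gauge fixing for LC models: order/orthogonalize components by
## SVD of the fitted bilinear term (deviance-invariant), rescale loadings
## to sum 1, shift each index to 0 at the reference year (absorbed into a)
gauge_fix_lc <- function(a, B, K, t0i) {
  r <- ncol(B)
  if (r == 2) {
    M <- B %*% t(K)
    sv <- svd(M, nu = 2, nv = 2)
    B <- sv$u
    K <- sv$v %*% diag(sv$d[1:2], 2)
  }
  for (i in seq_len(r)) {
    s <- sum(B[, i])
    if (abs(s) < 1e-10) {
      warning("loading vector sums to ~0; scale constraint left unapplied")
      next
    }
    B[, i] <- B[, i] / s
    K[, i] <- K[, i] * s
  }
  a <- a + as.vector(B %*% K[t0i, ])
  K <- sweep(K, 2, K[t0i, ])
  list(a = a, B = B, K = K)
}

finalize_fit <- function(surface, family, core, t0, r) {
  A <- length(surface$ages); T <- length(surface$years)
  mu <- stats::plogis(
    core$par$a + core$par$B %*% t(core$par$K) +
      if (identical(family, "H1"))
        matrix(core$par$gamma[core$cidx], nrow = A) else 0)
  pearson <- sum(((surface$d - surface$E * mu)^2 /
                    pmax(surface$E * mu * (1 - mu), 1e-300))[core$mask])
  np <- param_count(family, A, T)$total
  phi <- pearson / max(sum(core$mask) - np, 1)

  gamma <- NULL; cw <- NULL
  if (identical(family, "H1")) {
    cw <- core$cohort_w
    gamma <- ifelse(cw == 1L, core$par$gamma, NA_real_)
    names(gamma) <- names(cw)
  }
  new_lc_params(family, surface$ages, surface$years, core$par$a,
                core$par$B, core$par$K, t0, gamma = gamma,
                cohort_weights = cw, dispersion = phi,
                deviance = core$deviance, converged = core$converged,
                iterations = core$iterations)
}

#' Fit a Lee-Carter model with one or two bilinear terms
#'
#' Maximizes the binomial log-likelihood of the death counts with linear
#' predictor `a_x + sum_i b_x^(i) k_t^(i)` on the logit of `d/E`, by
#' alternating damped Newton updates over the per-age and per-year
#' parameter blocks (quasi-binomial point estimates coincide with binomial
#' ML; the dispersion is estimated once at convergence from the Pearson
#' statistic).  Cells with zero exposure are excluded.  After convergence
#' the parameters are gauge-fixed: components ordered and orthogonalized
#' through the SVD of the fitted bilinear term (two-term model), loadings
#' rescaled to sum to one, and each period index shifted to zero at the
#' reference year, with the shift absorbed into the age intercepts.  None
#' of these operations changes the fitted probabilities.
#'
#' @param surface A `mortality_surface`.
#' @param r Number of bilinear age-period terms (1 = classical model).
#' @param t0 Reference year of the location constraint (default: first
#'   year of the surface).
#' @param eps Probability clipping bound for the logit of the crude rates.
#' @param max_sweeps,tol Convergence control: stop when the relative
#'   deviance change per sweep falls below `tol` (default `1e-8`) or after
#'   `max_sweeps` sweeps (default 500, with a warning).
#' @param init Optional `lc_params` used as warm start (e.g. the fit to
#'   the original data when refitting bootstrap resamples); default is
#'   [init_svd()].
#' @return An `lc_params` object with elements `a`, `B` (A x r loadings),
#'   `K` (T x r period indices), `dispersion`, `deviance`.
#' @export
fit_lc <- function(surface, r = 1, t0 = NULL, eps = CLIP_EPS,
                   max_sweeps = 500, tol = 1e-8, init = NULL) {
  stopifnot(inherits(surface, "mortality_surface"))
  if (!r %in% 1:2) stop("r must be 1 or 2")
  if (any(rowSums(surface$E) == 0) || any(colSums(surface$E) == 0)) {
    stop("unidentifiable cells: an entire age row or year column has zero exposure")
  }
  t0 <- t0 %||% surface$years[1]
  t0i <- match(t0, surface$years)
  if (is.na(t0i)) stop("t0 is not a year of the surface")
  family <- if (r == 2) "LC2" else "LC1"
  init <- init %||% init_svd(surface, r, t0, eps)
  core <- fit_core(surface, family, r, t0, eps, max_sweeps, tol, init)
  gf <- gauge_fix_lc(core$par$a, core$par$B, core$par$K, t0i)
  core$par$a <- gf$a; core$par$B <- gf$B; core$par$K <- gf$K
  finalize_fit(surface, family, core, t0, r)
}

#' Fit the cohort-extended Lee-Carter model (two-stage)
#'
#' Stage 1 fixes the age intercepts at the year-means of the clipped
#' observed logits.  Stage 2 maximizes the weighted binomial likelihood of
#' `b_x k_t + gamma_{t-x}` around that fixed offset, with the first and
#' last five cohorts given weight zero (their cells are excluded from the
#' likelihood and their `gamma` reported as missing).  Constraints: the
#' period index is pinned to zero at the reference year during estimation
#' (with the intercepts fixed this is a real restriction, not gauge), the
#' loadings are positive (negative updates clipped to `1e-6`) and sum to
#' one.
#'
#' @inheritParams fit_lc
#' @return An `lc_params` object with `gamma` (named by cohort, `NA` for
#'   the ten zero-weight cohorts) and `cohort_weights`.
#' @export
fit_h1 <- function(surface, t0 = NULL, eps = CLIP_EPS, max_sweeps = 500,
                   tol = 1e-8, init = NULL) {
  stopifnot(inherits(surface, "mortality_surface"))
  t0 <- t0 %||% surface$years[1]
  t0i <- match(t0, surface$years)
  if (is.na(t0i)) stop("t0 is not a year of the surface")

  L <- logit_clip(ifelse(is.na(surface$q), 0.5, surface$q), eps)
  a_fixed <- rowMeans(L)                      # stage 1

  if (is.null(init)) {
    sv <- svd(L - a_fixed, nu = 1, nv = 1)
    b0 <- sv$u[, 1]; k0 <- sv$d[1] * sv$v[, 1]
    if (sum(b0) < 0) { b0 <- -b0; k0 <- -k0 }
    b0 <- pmax(b0, 1e-6); s <- sum(b0)
    b0 <- b0 / s; k0 <- k0 * s
    k0 <- k0 - k0[t0i]
    init <- list(a = a_fixed, B = matrix(b0), K = matrix(k0))
  } else {
    init <- list(a = a_fixed, B = init$B, K = init$K - init$K[t0i, 1])
  }
  core <- fit_core(surface, "H1", 1L, t0, eps, max_sweeps, tol, init)
  finalize_fit(surface, "H1", core, t0, 1L)
}

#' Fitted death counts under a fitted model
#'
#' `dhat = E * inverse-logit(predictor)`.  For the cohort model, cells in
#' zero-weight cohorts (whose `gamma` is not estimated) use `gamma = 0`,
#' so the fitted surface covers the full grid.
#'
#' @param params An `lc_params` fit.
#' @param surface The `mortality_surface` the model was fitted to (or one
#'   of identical shape).
#' @param gamma_fill Value substituted for unestimated cohort effects.
#' @return Matrix of fitted counts with `0 <= dhat <= E`.
#' @export
fitted_deaths <- function(params, surface, gamma_fill = 0) {
  stopifnot(inherits(params, "lc_params"), inherits(surface, "mortality_surface"))
  if (length(params$ages) != length(surface$ages) ||
      length(params$years) != length(surface$years)) {
    stop("parameter and surface shapes differ")
  }
  surface$E * stats::plogis(eta_from_params(params, surface, gamma_fill))
}

#' Model deviance, parameter count and dispersion
#'
#' Total deviance is the sum of squared deviance residuals over the cells
#' that entered the likelihood (positive exposure; for the cohort model
#' also weight-one cohorts).  The dispersion is the Pearson statistic
#' divided by the residual degrees of freedom.
#'
#' @param surface A `mortality_surface`.
#' @param params An `lc_params` fit of matching shape.
#' @return List with `deviance`, `n_params`, `dispersion`, `n_cells`.
#' @export
model_deviance <- function(surface, params) {
  stopifnot(inherits(params, "lc_params"), inherits(surface, "mortality_surface"))
  A <- length(surface$ages); T <- length(surface$years)
  if (length(params$ages) != A || length(params$years) != T) {
    stop("parameter and surface shapes differ")
  }
  mask <- surface$E > 0
  if (identical(params$family, "H1")) {
    gg <- gamma_grid(ifelse(params$cohort_weights == 1L, 1, NA), surface)
    mask <- mask & !is.na(gg)
  }
  mu <- stats::plogis(eta_from_params(params, surface))
  dhat <- surface$E * mu
  dev <- sum(binom_dev_cells(surface$d, dhat, surface$E)[mask])
  np <- param_count(params$family, A, T)
  pearson <- sum(((surface$d - dhat)^2 /
                    pmax(surface$E * mu * (1 - mu), 1e-300))[mask])
  list(deviance = dev, n_params = np$total,
       dispersion = pearson / max(sum(mask) - np$total, 1),
       n_cells = sum(mask))
}
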