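## Residual block bootstrap: deviance residuals of the fitted surface,
## 2-D resampling in non-overlapping rectangular blocks (preserving local
## age-period dependence), and inversion back to resampled death counts.

#' Deviance residuals of a binomial fit
#'
#' `r = sign(d - dhat) * sqrt(2 [d log(d/dhat) + (E-d) log((E-d)/(E-dhat))])`
#' with the `0 log 0 = 0` convention.  The sum of squared residuals over
#' in-likelihood cells equals the model deviance.
#'
#' @param d Observed death counts (matrix).
#' @param dhat Fitted death counts, strictly inside `(0, E)` on cells of
#'   interest; cells where `dhat` is 0 or `E` get a missing residual.
#' @param E Exposures.
#' @param mask Optional logical matrix of in-likelihood cells (residuals
#'   elsewhere set missing); default: all cells with `E > 0`.
#' @return Object of class `residual_matrix`: list with `r` (residuals)
#'   and `mask`.
#' @export
deviance_residuals <- function(d, dhat, E, mask = NULL) {
  d <- as.matrix(d); dhat <- as.matrix(dhat); E <- as.matrix(E)
  stopifnot(all(dim(d) == dim(dhat)), all(dim(d) == dim(E)))
  if (any(d < 0 | d > E)) stop("need 0 <= d <= E")
  mask <- mask %||% (E > 0)
  bad <- mask & (dhat <= 0 | dhat >= E)
  if (any(bad)) {
    warning(sprintf("%d cells have fitted deaths at 0 or E; residuals set missing",
                    sum(bad)))
    mask <- mask & !bad
  }
  r <- matrix(NA_real_, nrow(d), ncol(d))
  ok <- mask
  r[ok] <- sign(d[ok] - dhat[ok]) *
    sqrt(pmax(binom_dev_cells(d, dhat, E)[ok], 0))
  structure(list(r = r, mask = mask), class = "residual_matrix")
}

#' Block-resampling specification
#'
#' @param height Block extent in ages.
#' @param width Block extent in years.
#' @param seed Optional integer seed making the resample reproducible.
#' @return Object of class `block_spec`.
#' @export
block_spec <- function(height, width, seed = NULL) {
  stopifnot_scalar_count(height, "height")
  stopifnot_scalar_count(width, "width")
  structure(list(height = as.integer(height), width = as.integer(width),
                 seed = seed), class = "block_spec")
}

#' Resample a residual matrix in non-overlapping rectangular blocks
#'
#' The target array (same shape as the input) is tiled by `height x width`
#' blocks anchored at the top-left corner, edge blocks truncated.  Each
#' target block of effective size `h' x w'` is filled with the `h' x w'`
#' rectangle extending to the southeast of an anchor cell chosen uniformly
#' among all positions where that rectangle fits inside the original
#' array; anchors are drawn independently across blocks.  `1 x 1` blocks
#' reduce to the iid residual bootstrap; a block as large as the array
#' reproduces the input exactly.
#'
#' @param resid A `residual_matrix` (its `mask` is carried over unchanged:
#'   masked-out cells participate in the geometry and are re-masked by the
#'   downstream refit).
#' @param spec A `block_spec`.
#' @return A `residual_matrix` with resampled values.
#' @export
resample_blocks <- function(resid, spec) {
  stopifnot(inherits(resid, "residual_matrix"), inherits(spec, "block_spec"))
  A <- nrow(resid$r); T <- ncol(resid$r)
  h <- spec$height; w <- spec$width
  if (h > A || w > T) stop("block larger than the residual array")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  out <- matrix(NA_real_, A, T)
  row_starts <- seq.int(1L, A, by = h)
  col_starts <- seq.int(1L, T, by = w)
  for (r0 in row_starts) {
    hh <- min(h, A - r0 + 1L)
    for (c0 in col_starts) {
      ww <- min(w, T - c0 + 1L)
      ar <- sample.int(A - hh + 1L, 1L)
      ac <- sample.int(T - ww + 1L, 1L)
      out[r0:(r0 + hh - 1L), c0:(c0 + ww - 1L)] <-
        resid$r[ar:(ar + hh - 1L), ac:(ac + ww - 1L)]
    }
  }
  structure(list(r = out, mask = resid$mask), class = "residual_matrix")
}

#' Invert resampled residuals to death counts
#'
#' Solves, cell by cell, the deviance equation
#' `2 [d log(d/dhat) + (E-d) log((E-d)/(E-dhat))] = rhat^2` for `d`,
#' taking the root on the side of `dhat` indicated by `sign(rhat)`.  The
#' left side is convex in `d` with minimum 0 at `dhat`, so bisection on
#' `[dhat, E]` (or `[0, dhat]`) converges; when `rhat^2` exceeds the value
#' attainable at the boundary the count is clipped to `E` (or 0).  The
#' output is real-valued (not rounded): the quasi-binomial refit accepts
#' continuous counts.
#'
#' @param rhat A `residual_matrix` of (resampled) residuals.
#' @param dhat Fitted death counts, strictly inside `(0, E)` on masked-in
#'   cells.
#' @param E Exposures.
#' @param tol Bisection tolerance as a fraction of `E` (default `1e-9`).
#' @return Matrix of resampled death counts; cells with a non-finite
#'   residual are set to `dhat` with a warning, masked-out cells are set
#'   to `dhat`.
#' @export
invert_to_deaths <- function(rhat, dhat, E, tol = 1e-9) {
  stopifnot(inherits(rhat, "residual_matrix"))
  dhat <- as.matrix(dhat); E <- as.matrix(E)
  r <- rhat$r
  mask <- rhat$mask
  bad <- mask & !is.finite(r)
  if (any(bad)) {
    warning(sprintf("%d non-finite residuals on in-mask cells; counts set to fitted values",
                    sum(bad)))
  }
  use <- mask & is.finite(r)
  out <- dhat                            # default: masked-out / bad cells
  if (any(use)) {
    target <- (r[use])^2
    dh <- dhat[use]; Ex <- E[use]
    pos <- r[use] >= 0
    lo <- ifelse(pos, dh, 0)
    hi <- ifelse(pos, Ex, dh)
    hfun <- function(x) binom_dev_cells(x, dh, Ex)
    ## clip where the target exceeds the deviance at the boundary
    hb <- hfun(ifelse(pos, Ex, 0))
    clip <- target >= hb
    res <- numeric(length(dh))
    res[clip] <- ifelse(pos, Ex, 0)[clip]
    if (any(!clip)) {
      l <- lo[!clip]; u <- hi[!clip]
      dhn <- dh[!clip]; Exn <- Ex[!clip]; tn <- target[!clip]
      pn <- pos[!clip]
      for (it in 1:100) {
        mid <- (l + u) / 2
        hm <- binom_dev_cells(mid, dhn, Exn)
        ## on the increasing branch (d > dhat) move up when h < target;
        ## on the decreasing branch move down when h < target
        up <- (hm < tn) == pn
        l <- ifelse(up, mid, l)
        u <- ifelse(up, u, mid)
        if (max((u - l) / pmax(Exn, 1)) <= tol) break
      }
      res[!clip] <- (l + u) / 2
    }
    out[use] <- res
  }
  out
}

#' Two-dimensional correlogram of a residual matrix
#'
#' Mean-removed sample autocorrelations of the residual array at each
#' (age-lag, year-lag) offset, normalized by the overall variance; the
#' value at lag (0, 0) is 1.  Negative year lags capture anti-diagonal
#' (cohort-crossing) dependence; by symmetry only non-negative age lags
#' are reported.  Used as a numeric diagnostic that a block size preserves
#' the dependence structure of the original residuals.
#'
#' @param resid A `residual_matrix` (only masked-in finite cells are used;
#'   pairs involving other cells are dropped).
#' @param max_lag_age,max_lag_year Maximum lags (must be smaller than the
#'   array dimensions).
#' @return Matrix of autocorrelations with rows `0..max_lag_age` (age lag)
#'   and columns `-max_lag_year..max_lag_year` (year lag).
#' @export
residual_correlogram <- function(resid, max_lag_age = 3, max_lag_year = 3) {
  stopifnot(inherits(resid, "residual_matrix"))
  A <- nrow(resid$r); T <- ncol(resid$r)
  if (max_lag_age >= A || max_lag_year >= T) stop("lags must be smaller than the array")
  x <- resid$r
  x[!resid$mask] <- NA
  mu <- mean(x, na.rm = TRUE)
  v <- mean((x - mu)^2, na.rm = TRUE)
  if (!is.finite(v) || v <= 0) stop("zero-variance residuals: correlation undefined")
  xc <- x - mu
  lags_a <- 0:max_lag_age
  lags_y <- (-max_lag_year):max_lag_year
  out <- matrix(NA_real_, length(lags_a), length(lags_y),
                dimnames = list(age_lag = lags_a, year_lag = lags_y))
  for (i in seq_along(lags_a)) {
    la <- lags_a[i]
    for (j in seq_along(lags_y)) {
      ly <- lags_y[j]
      r1 <- 1:(A - la); r2 <- r1 + la
      if (ly >= 0) { c1 <- 1:(T - ly); c2 <- c1 + ly }
      else { c1 <- (1 - ly):T; c2 <- c1 + ly }
      prod <- xc[r1, c1, drop = FALSE] * xc[r2, c2, drop = FALSE]
      out[i, j] <- mean(prod, na.rm = TRUE) / v
    }
  }
  out
}
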