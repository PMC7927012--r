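## End-to-end crossed experiment: for each residual source S, fit S to the
## data, block-resample its deviance residuals, invert to resampled death
## counts, refit every fitting model M on those counts, project the
## indices with ARIMA and evaluate the indicator curves -- giving the
## (model x sample) design of replicate curves that the functional ANOVA
## compares.

#' Crossed design cells of an experiment
#'
#' @param models Fitting-model labels.
#' @param sources Residual-source labels.
#' @return Data frame with one row per (model, source) combination.
#' @export
design_cells <- function(models = c("LC1", "LC2", "H1"),
                         sources = c("LC1", "LC2", "H1")) {
  expand.grid(model = models, residual_source = sources,
              stringsAsFactors = FALSE)
}

#' Default block sizes for the residual bootstrap
#'
#' 3 ages x 9 years for the one- and two-term model sources and
#' 3 ages x 14 years for the cohort-model source on a 100 x 22 surface,
#' scaled proportionally (and floored at 1) for smaller surfaces.
#'
#' @param A,T Surface dimensions.
#' @return Named list of `c(height, width)` per source.
#' @export
default_block_sizes <- function(A, T) {
  sc <- function(base, dim, ref) max(1L, min(dim, as.integer(round(base * dim / ref))))
  list(LC1 = c(sc(3, A, 100), sc(9, T, 22)),
       LC2 = c(sc(3, A, 100), sc(9, T, 22)),
       H1  = c(sc(3, A, 100), sc(14, T, 22)))
}

fit_model <- function(surface, model, t0 = NULL, init = NULL, ...) {
  switch(model,
         LC1 = fit_lc(surface, r = 1, t0 = t0, init = init, ...),
         LC2 = fit_lc(surface, r = 2, t0 = t0, init = init, ...),
         H1  = fit_h1(surface, t0 = t0, init = init, ...),
         stop("unknown model ", model))
}

## ARIMA specifications for the indices of one fitted model: random walk
## with drift for the first period index, AICc grid for a second index
## and for the cohort series
index_arima_specs <- function(fit) {
  specs <- list()
  k1 <- try_arima(fit$K[, 1], c(0, 1, 0), TRUE)
  if (is.null(k1)) k1 <- refit_arima(fit$K[, 1], structure(list(fit = NULL),
                                                           class = "arima_spec"))
  specs$k <- list(k1)
  if (ncol(fit$K) == 2) specs$k[[2]] <- select_arima(fit$K[, 2])
  if (identical(fit$family, "H1")) {
    est <- fit$gamma[!is.na(fit$gamma)]
    specs$gamma <- select_arima(as.numeric(est))
  }
  specs
}

## forecast the indicator curves of one fitted replicate
forecast_replicate <- function(fit, specs, horizon, e_ages, radix) {
  r <- ncol(fit$K)
  kf <- matrix(NA_real_, horizon, r)
  for (i in seq_len(r)) {
    sp <- refit_arima(fit$K[, i], specs$k[[i]])
    kf[, i] <- forecast_index(sp, horizon)
  }
  future_years <- max(fit$years) + seq_len(horizon)
  gf <- NULL
  if (identical(fit$family, "H1")) {
    gf <- suppressWarnings(forecast_gamma(fit$gamma, horizon,
                                          spec = specs$gamma))
  }
  qf <- project_probabilities(fit, kf, future_years, gamma_future = gf)
  compute_indicators(qf, e_ages = e_ages, radix = radix)
}

#' Run the crossed block-bootstrap experiment
#'
#' For each residual source: fits the source model, computes full-grid
#' deviance residuals and fitted deaths; for each bootstrap replicate,
#' block-resamples the residuals and inverts them to resampled death
#' counts; refits every fitting model on those counts (warm-started at the
#' original fit) and projects its indicator curves over the horizon.
#' Assembles one `indicator_curve_set` per indicator over all
#' (model, source) cells, percentile confidence intervals per cell, and
#' the functional ANOVA with pairwise comparisons per indicator.
#'
#' @param surface A `mortality_surface`.
#' @param models Fitting models (subset of `LC1`, `LC2`, `H1`).
#' @param sources Residual sources (same candidates).
#' @param n_boot Bootstrap replicates per cell (N, at least 2).
#' @param horizon Forecast years beyond the fitted period.
#' @param block_sizes Named list of `c(ages, years)` block extents per
#'   source; default [default_block_sizes()].
#' @param e_ages Ages for the life-expectancy indicators.
#' @param radix Life-table radix.
#' @param K Random projections for the functional ANOVA.
#' @param alpha Test level.
#' @param seed Master seed; every random stage derives its stream from it.
#' @param max_fail Largest tolerated fraction of failed replicates.
#' @param run_fanova Set `FALSE` to skip the testing stage (e.g. when a
#'   single cell is run).
#' @return Object of class `mortality_experiment`: list with `fits`,
#'   `curve_sets` (per indicator), `intervals` (long data frame),
#'   `fanova` and `pairwise` (per indicator), `arima_specs`, `failed`
#'   (dropped replicate indices) and the configuration.
#' @export
run_experiment <- function(surface,
                           models = c("LC1", "LC2", "H1"),
                           sources = c("LC1", "LC2", "H1"),
                           n_boot = 10, horizon = 20,
                           block_sizes = NULL, e_ages = c(0, 65),
                           radix = 1e5, K = 30, alpha = 0.05, seed = 1,
                           max_fail = 0.1, run_fanova = TRUE) {
  stopifnot(inherits(surface, "mortality_surface"))
  if (n_boot < 2) stop("need at least 2 bootstrap replicates")
  stopifnot_scalar_count(horizon, "horizon")
  models <- match.arg(models, c("LC1", "LC2", "H1"), several.ok = TRUE)
  sources <- match.arg(sources, c("LC1", "LC2", "H1"), several.ok = TRUE)
  A <- length(surface$ages); T <- length(surface$years)
  block_sizes <- block_sizes %||% default_block_sizes(A, T)
  for (s in sources) {
    bs <- block_sizes[[s]]
    if (is.null(bs) || bs[1] > A || bs[2] > T) {
      stop("invalid block size for source ", s)
    }
  }
  if (max(surface$ages) < max(e_ages)) {
    stop("surface does not extend to the oldest life-expectancy age requested")
  }

  ## original fits and fixed ARIMA orders, one per distinct model
  all_models <- union(models, sources)
  fits <- lapply(stats::setNames(all_models, all_models),
                 function(m) fit_model(surface, m))
  specs <- lapply(fits[models], index_arima_specs)

  indicators <- c(paste0("e", e_ages), "modal", "gini")
  curves <- array(NA_real_,
                  dim = c(length(models), length(sources), n_boot, horizon,
                          length(indicators)),
                  dimnames = list(model = models, source = sources,
                                  rep = NULL, year = NULL,
                                  indicator = indicators))
  failed <- logical(n_boot)

  for (si in seq_along(sources)) {
    s <- sources[si]
    sfit <- fits[[s]]
    dhat <- fitted_deaths(sfit, surface)          # gamma = 0 off-mask (H1)
    resid <- deviance_residuals(surface$d, dhat, surface$E)
    bs <- block_sizes[[s]]
    for (n in seq_len(n_boot)) {
      spec <- block_spec(bs[1], bs[2], seed = derive_seed(seed, si, n))
      rhat <- resample_blocks(resid, spec)
      d_n <- invert_to_deaths(rhat, dhat, surface$E)
      surf_n <- mortality_surface(surface$ages, surface$years, surface$E, d_n)
      for (mi in seq_along(models)) {
        m <- models[mi]
        ind <- tryCatch({
          refit <- suppressWarnings(fit_model(surf_n, m, init = fits[[m]]))
          forecast_replicate(refit, specs[[m]], horizon, e_ages, radix)
        }, error = function(e) {
          message(sprintf("replicate %d (model %s, source %s) failed: %s",
                          n, m, s, conditionMessage(e)))
          NULL
        })
        if (is.null(ind)) failed[n] <- TRUE
        else curves[mi, si, n, , ] <- ind
      }
    }
  }

  if (mean(failed) > max_fail) {
    stop(sprintf("%d of %d replicates failed", sum(failed), n_boot))
  }
  keep <- which(!failed)
  curves <- curves[, , keep, , , drop = FALSE]

  curve_sets <- lapply(stats::setNames(indicators, indicators), function(ind) {
    arr <- curves[, , , , ind, drop = FALSE]
    dim(arr) <- dim(curves)[1:4]
    dimnames(arr) <- dimnames(curves)[1:4]
    indicator_curve_set(ind, max(surface$years) + seq_len(horizon), arr)
  })

  intervals <- do.call(rbind, lapply(curve_sets, intervals_long))
  rownames(intervals) <- NULL

  fanova <- NULL; pairwise <- NULL
  if (run_fanova && length(models) > 1 && length(sources) > 1) {
    fanova <- list(); pairwise <- list()
    for (ind in indicators) {
      cs <- curve_sets[[ind]]
      fa <- fanova_test(cs, K = K, alpha = alpha,
                        seed = derive_seed(seed, 9090, match(ind, indicators)))
      fanova[[ind]] <- fa
      pairwise[[ind]] <- list(
        model = pairwise_comparisons(cs, "model", alpha = alpha,
                                     directions = fa$directions),
        sample = pairwise_comparisons(cs, "sample", alpha = alpha,
                                      directions = fa$directions))
    }
  }

  structure(
    list(fits = fits, arima_specs = specs, curve_sets = curve_sets,
         intervals = intervals, fanova = fanova, pairwise = pairwise,
         failed = which(failed),
         config = list(models = models, sources = sources, n_boot = n_boot,
                       horizon = horizon, block_sizes = block_sizes,
                       e_ages = e_ages, radix = radix, K = K, alpha = alpha,
                       seed = seed)),
    class = "mortality_experiment"
  )
}

#' @export
print.mortality_experiment <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Crossed mortality experiment: %d models x %d sources, N = %d, horizon %d\n",
              length(cfg$models), length(cfg$sources), cfg$n_boot,
              cfg$horizon))
  if (!is.null(x$fanova)) {
    for (ind in names(x$fanova)) {
      fa <- x$fanova[[ind]]
      cat(sprintf("  %-6s model %s, sample %s, interaction %s\n", ind,
                  fa$decisions[1], fa$decisions[2], fa$decisions[3]))
    }
  }
  invisible(x)
}
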