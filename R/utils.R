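#' Logit with boundary clipping
#'
#' Clips probabilities into `[eps, 1 - eps]` before applying the logit, so
#' that crude probabilities of 0 or 1 (empty cells, extinct ages) map to
#' large finite values instead of `-Inf`/`Inf`.
#'
#' @param q Numeric vector or matrix of probabilities in `[0, 1]`.
#' @param eps Clipping bound (default `1e-8`).
#' @return Object of the same shape as `q` with `log(q/(1-q))` applied
#'   elementwise after clipping.
#' @export
logit_clip <- function(q, eps = 1e-8) {
  if (any(q < 0 | q > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]")
  }
  q <- pmin(pmax(q, eps), 1 - eps)
  log(q / (1 - q))
}

#' Inverse logit
#'
#' @param x Numeric vector or matrix on the logit scale.
#' @return Probabilities `exp(x)/(1 + exp(x))`, computed stably.
#' @export
inv_logit <- function(x) {
  stats::plogis(x)
}

## integer-safe seed derivation: mixes a master seed with stream labels so
## each (replicate, design-cell) pair gets its own reproducible RNG stream
derive_seed <- function(master, ...) {
  parts <- c(master, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + as.double(p) * 2654435761) %% 2147483647
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x)) {
    stop(sprintf("`%s` must be a single positive integer", name))
  }
}
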