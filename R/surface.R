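#' Mortality surface: age-by-year exposures, deaths and crude probabilities
#'
#' A rectangular grid indexed by contiguous integer ages (rows) and
#' contiguous calendar years (columns).  Death counts may be non-integer
#' (the bootstrap inversion produces continuous counts); crude
#' probabilities are `d / E` wherever exposure is positive.
#'
#' @param ages Contiguous integer ages (length A).
#' @param years Contiguous integer years (length T).
#' @param E Exposure-to-risk matrix, A x T, non-negative.
#' @param d Death-count matrix, A x T, with `0 <= d <= E` elementwise.
#' @return Object of class `mortality_surface`: list with `ages`, `years`,
#'   `E`, `d` and `q = d/E` (`NA` where `E = 0`).
#' @export
mortality_surface <- function(ages, years, E, d) {
  ages <- as.integer(ages); years <- as.integer(years)
  if (any(diff(ages) != 1L)) stop("ages must be contiguous integers")
  if (any(diff(years) != 1L)) stop("years must be contiguous integers")
  E <- as.matrix(E); d <- as.matrix(d)
  if (!all(dim(E) == c(length(ages), length(years))) ||
      !all(dim(d) == dim(E))) {
    stop("E and d must both be ages x years matrices")
  }
  if (any(E < 0)) stop("exposures must be non-negative")
  if (any(d < -1e-9) || any(d > E + 1e-9 * pmax(E, 1))) {
    stop("death counts must satisfy 0 <= d <= E")
  }
  d <- pmin(pmax(d, 0), E)
  q <- ifelse(E > 0, d / E, NA_real_)
  dimnames(E) <- dimnames(d) <- dimnames(q) <- list(ages, years)
  structure(list(ages = ages, years = years, E = E, d = d, q = q),
            class = "mortality_surface")
}

#' @export
print.mortality_surface <- function(x, ...) {
  cat(sprintf("Mortality surface: %d ages (%d..%d) x %d years (%d..%d)\n",
              length(x$ages), min(x$ages), max(x$ages),
              length(x$years), min(x$years), max(x$years)))
  invisible(x)
}

#' Cohort (year of birth) index for every cell of a surface
#'
#' @param surface A `mortality_surface`.
#' @return Integer matrix of `year - age`, same shape as the surface.
#' @export
cohort_matrix <- function(surface) {
  outer(-surface$ages, surface$years, `+`)
}

#' All cohorts present in a surface
#'
#' @param surface A `mortality_surface`.
#' @return Sorted integer vector of the `T + A - 1` distinct birth years.
#' @export
cohort_range <- function(surface) {
  seq.int(min(surface$years) - max(surface$ages),
          max(surface$years) - min(surface$ages))
}
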