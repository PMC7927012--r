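## Plain-text interchange: surfaces as age-by-year CSV matrices (first
## column "age", remaining headers calendar years), fitted parameters as
## JSON, results as long CSV tables.

surface_matrix_to_df <- function(m, ages, years) {
  df <- data.frame(age = ages, m, check.names = FALSE)
  names(df) <- c("age", years)
  df
}

df_to_surface_matrix <- function(df, what) {
  if (names(df)[1] != "age") stop(sprintf("%s file: first column must be 'age'", what))
  ages <- df$age
  if (any(diff(ages) != 1)) stop(sprintf("%s file: ages are not contiguous", what))
  years <- suppressWarnings(as.integer(names(df)[-1]))
  if (anyNA(years)) {
    stop(sprintf("%s file: non-year column header '%s'", what,
                 names(df)[-1][which(is.na(years))[1]]))
  }
  if (any(diff(years) != 1)) stop(sprintf("%s file: years are not contiguous", what))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(m)) stop(sprintf("%s file: missing values", what))
  list(m = m, ages = ages, years = years)
}

#' Write or read a mortality surface as CSV matrices
#'
#' Exposures and death counts (or probabilities) are stored as separate
#' CSV files with schema: first column `age`, remaining column headers
#' the calendar years.  Either a deaths file or a probabilities file may
#' be given on reading; with probabilities, counts are reconstructed as
#' `d = q * E`.
#'
#' @param surface A `mortality_surface`.
#' @param e_path Path of the exposures CSV.
#' @param d_path Path of the deaths CSV (write: always written; read:
#'   alternative to `q_path`).
#' @param q_path Path of a probabilities CSV (read only).
#' @return `read_surface` returns a `mortality_surface`; `write_surface`
#'   returns the paths invisibly.
#' @export
write_surface <- function(surface, e_path, d_path) {
  stopifnot(inherits(surface, "mortality_surface"))
  utils::write.csv(surface_matrix_to_df(surface$E, surface$ages, surface$years),
                   e_path, row.names = FALSE)
  utils::write.csv(surface_matrix_to_df(surface$d, surface$ages, surface$years),
                   d_path, row.names = FALSE)
  invisible(c(e_path, d_path))
}

#' @rdname write_surface
#' @export
read_surface <- function(e_path, d_path = NULL, q_path = NULL) {
  if (is.null(d_path) == is.null(q_path)) {
    stop("give exactly one of d_path or q_path")
  }
  ein <- df_to_surface_matrix(utils::read.csv(e_path, check.names = FALSE), "exposure")
  if (!is.null(d_path)) {
    din <- df_to_surface_matrix(utils::read.csv(d_path, check.names = FALSE), "deaths")
    d <- din$m
    src <- din
  } else {
    qin <- df_to_surface_matrix(utils::read.csv(q_path, check.names = FALSE), "probability")
    d <- qin$m * ein$m
    src <- qin
  }
  if (!identical(src$ages, ein$ages) || !identical(src$years, ein$years)) {
    stop("exposure and deaths/probability files cover different grids")
  }
  mortality_surface(ein$ages, ein$years, ein$m, d)
}

#' Serialize fitted parameters to JSON (and back)
#'
#' @param params An `lc_params`.
#' @param path JSON file path.
#' @return `read_params_json` returns an `lc_params`; the writer returns
#'   `path` invisibly.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "lc_params"))
  obj <- list(family = params$family, t0 = params$t0,
              ages = params$ages, years = params$years,
              a = params$a, B = params$B, K = params$K,
              dispersion = params$dispersion, deviance = params$deviance)
  if (!is.null(params$gamma)) {
    obj$gamma <- as.list(params$gamma[!is.na(params$gamma)])
    obj$cohort_weights <- as.list(params$cohort_weights)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  gamma <- NULL; cw <- NULL
  if (!is.null(obj$gamma)) {
    cw <- unlist(obj$cohort_weights)
    gamma <- stats::setNames(rep(NA_real_, length(cw)), names(cw))
    gamma[names(obj$gamma)] <- unlist(obj$gamma)
  }
  new_lc_params(obj$family, as.integer(obj$ages), as.integer(obj$years),
                obj$a, as.matrix(obj$B), as.matrix(obj$K), obj$t0,
                gamma = gamma, cohort_weights = cw,
                dispersion = obj$dispersion, deviance = obj$deviance)
}

#' Long-format tables of an experiment's curves and intervals
#'
#' @param curveset An `indicator_curve_set`.
#' @return `curves_long` returns a data frame with columns `indicator`,
#'   `model`, `residual_source`, `replicate`, `year`, `value`;
#'   `intervals_long` returns `indicator`, `model`, `residual_source`,
#'   `year`, `lower`, `upper` using [percentile_ci()] per design cell.
#' @export
curves_long <- function(curveset) {
  stopifnot(inherits(curveset, "indicator_curve_set"))
  d <- dim(curveset$curves)
  dn <- dimnames(curveset$curves)
  g <- expand.grid(model = dn[[1]], residual_source = dn[[2]],
                   replicate = seq_len(d[3]), year = curveset$years,
                   stringsAsFactors = FALSE)
  g$indicator <- curveset$indicator
  g$value <- as.vector(curveset$curves)
  g[, c("indicator", "model", "residual_source", "replicate", "year", "value")]
}

#' @rdname curves_long
#' @export
intervals_long <- function(curveset) {
  stopifnot(inherits(curveset, "indicator_curve_set"))
  d <- dim(curveset$curves)
  dn <- dimnames(curveset$curves)
  out <- list()
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      ci <- percentile_ci(curveset$curves[i, j, , ])
      out[[length(out) + 1]] <- data.frame(
        indicator = curveset$indicator, model = dn[[1]][i],
        residual_source = dn[[2]][j], year = curveset$years,
        lower = ci$lower, upper = ci$upper, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
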