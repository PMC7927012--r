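#' Build a period life table from death probabilities
#'
#' Constructs the synthetic-cohort (period) life table for one calendar
#' year from a vector of one-year death probabilities over contiguous
#' integer ages `0..omega`.  The table is closed by forcing the final
#' probability to 1, so the cohort is extinct at `omega + 1`.  Those dying
#' within an interval are assumed to live half of it, at every age:
#' `L[x] = l[x] - 0.5 * d[x]`.
#'
#' @param q Numeric vector of death probabilities in `[0, 1]`, one per age
#'   starting at age 0.  The last entry is overwritten with 1 (closure).
#' @param radix Starting cohort size `l[0]` (default 100000).
#' @param a_frac Fraction of the age interval lived by those dying in it
#'   (default 0.5, applied uniformly including age 0 and the open interval).
#' @return An object of class `period_life_table`: a list with components
#'   `ages`, `q`, `l` (survivors at exact age), `d` (deaths in interval),
#'   `L` (person-years in interval), `T` (person-years at and above age),
#'   `e` (remaining life expectancy, `NA` where `l = 0`) and `radix`.
#' @examples
#' lt <- build_period_table(c(0.5, 1), radix = 1000)
#' lt$e[1]  # life expectancy at birth = 1 year
#' @export
build_period_table <- function(q, radix = 1e5, a_frac = 0.5) {
  if (length(q) == 0L || !is.numeric(q) || anyNA(q)) {
    stop("`q` must be a non-empty numeric vector without NAs")
  }
  if (any(q < 0 | q > 1)) stop("death probabilities must lie in [0, 1]")
  if (!is.numeric(radix) || radix <= 0) stop("`radix` must be positive")
  omega <- length(q) - 1L
  q[omega + 1L] <- 1                      # closure: extinct at omega + 1
  l <- radix * cumprod(c(1, 1 - q[-(omega + 1L)]))
  d <- l * q
  L <- l - a_frac * d
  Tx <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, Tx / l, NA_real_)
  structure(
    list(ages = 0:omega, q = q, l = l, d = d, L = L, T = Tx, e = e,
         radix = radix),
    class = "period_life_table"
  )
}

#' @export
as.data.frame.period_life_table <- function(x, ...) {
  data.frame(age = x$ages, q = x$q, l = x$l, d = x$d, L = x$L, T = x$T,
             e = x$e)
}

#' @export
print.period_life_table <- function(x, ...) {
  omega <- max(x$ages)
  cat(sprintf("Period life table: ages 0..%d, radix %g, e0 = %.3f\n",
              omega, x$radix, x$e[1]))
  invisible(x)
}

#' Remaining life expectancy at an age
#'
#' Returns `T[x] / l[x]`, the average number of years left to members of
#' the synthetic cohort alive at exact age `x`.
#'
#' @param table A `period_life_table`.
#' @param x Integer age between 0 and `omega`.
#' @return Life expectancy in years (non-negative).
#' @export
life_expectancy <- function(table, x) {
  stopifnot(inherits(table, "period_life_table"))
  if (!x %in% table$ages) stop("age outside the table range")
  i <- match(x, table$ages)
  if (table$l[i] <= 0) stop("life expectancy undefined: no survivors at this age")
  table$T[i] / table$l[i]
}

#' Modal age at death
#'
#' The adult modal age at death: the age above 5 (i.e. age >= 6) with the
#' maximum synthetic-cohort death count.  Ties are broken by the smallest
#' such age.  Restricting to ages above 5 excludes the infant-mortality
#' peak so the indicator tracks the adult hump of the death distribution.
#'
#' @param table A `period_life_table` with `omega >= 6`.
#' @return Integer age.
#' @export
modal_age <- function(table) {
  stopifnot(inherits(table, "period_life_table"))
  eligible <- table$ages >= 6L
  if (!any(eligible)) stop("modal age needs a table extending beyond age 5")
  ages <- table$ages[eligible]
  d <- table$d[eligible]
  ages[which.max(d)]                      # which.max takes the first maximum
}

#' Lorenz curve of the distribution of ages at death
#'
#' For each age `x`, `f[x] = 1 - l[x]/l[0]` is the proportion of the
#' synthetic cohort dead before age `x`, and
#' `g[x] = (T[0] - T[x] - x*l[x]) / T[0]` is the share of total
#' person-years that was lived by those already dead.  A terminal point
#' `(1, 1)` is appended, representing extinction at `omega + 1`.
#'
#' @param table A `period_life_table` with `T[0] > 0`.
#' @return An object of class `lorenz_curve`: list with `f` and `g`
#'   (non-decreasing, `f[1] = g[1] = 0`, final entries 1, `g <= f`).
#' @export
lorenz_points <- function(table) {
  stopifnot(inherits(table, "period_life_table"))
  T0 <- table$T[1]
  if (T0 <= 0) stop("degenerate table: no person-years lived")
  f <- 1 - table$l / table$l[1]
  g <- (T0 - table$T - table$ages * table$l) / T0
  structure(list(f = c(f, 1), g = c(g, 1)), class = "lorenz_curve")
}

#' Gini index of lifespan inequality
#'
#' Discrete Lorenz-curve estimator: the ratio of `sum(f - g)` to `sum(f)`
#' with both sums over ages `0..omega-1`.  The index is 0 when every
#' member of the cohort dies at the same age and approaches 1 when almost
#' all die at birth.
#'
#' @param table A `period_life_table`.
#' @return Gini index in `[0, 1]`.  If the denominator is zero (nobody
#'   dies before the last age interval, so the Lorenz points all sit at
#'   the origin) the index is 0 with a warning.
#' @export
gini_index <- function(table) {
  stopifnot(inherits(table, "period_life_table"))
  lz <- lorenz_points(table)
  omega <- max(table$ages)
  idx <- seq_len(omega)                   # Lorenz indices for ages 0..omega-1
  denom <- sum(lz$f[idx])
  if (denom <= 0) {
    warning("all deaths occur in the final age interval; Gini index is 0")
    return(0)
  }
  sum(lz$f[idx] - lz$g[idx]) / denom
}

#' Write or read a period life table as CSV
#'
#' Plain-text schema `age,q,l,d,L,T,e`, one file per calendar year.
#'
#' @param table A `period_life_table`.
#' @param path File path.
#' @return `read_lifetable_csv` returns a `period_life_table` rebuilt from
#'   the stored `q` column (and radix `l[1]`); `write_lifetable_csv`
#'   returns `path` invisibly.
#' @export
write_lifetable_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lifetable_csv
#' @export
read_lifetable_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("age", "q", "l", "d", "L", "T", "e")
  if (!all(need %in% names(df))) {
    stop("life-table CSV must have columns ", paste(need, collapse = ","))
  }
  build_period_table(df$q, radix = df$l[1])
}
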