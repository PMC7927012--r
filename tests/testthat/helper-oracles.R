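# Independent brute-force oracles used across test files.  They do direct
# bookkeeping over the discrete distribution of ages at death (die in
# interval [y, y+1) => live y + 0.5 years) and never call the package's
# life-table recursions.

# distribution of age-at-death interval implied by q (q closed with q[omega]=1)
oracle_death_dist <- function(q) {
  q[length(q)] <- 1
  surv <- cumprod(c(1, 1 - q))[seq_along(q)]   # P(alive at start of interval)
  surv * q
}

# life expectancy at birth by direct expectation of lifetime
oracle_e0 <- function(q) {
  p <- oracle_death_dist(q)
  ages <- seq_along(q) - 1
  sum(p * (ages + 0.5))
}

# life expectancy at age x: condition on survival to x
oracle_ex <- function(q, x) {
  p <- oracle_death_dist(q)
  ages <- seq_along(q) - 1
  keep <- ages >= x
  sum(p[keep] * (ages[keep] + 0.5 - x)) / sum(p[keep])
}

# Lorenz points by person-level accumulation: f = share dead before age x,
# g = share of total person-years lived by those already dead
oracle_lorenz <- function(q, radix = 1e5) {
  p <- oracle_death_dist(q)
  d <- radix * p
  ages <- seq_along(q) - 1
  years_per_death <- ages + 0.5
  T0 <- sum(d * years_per_death)
  f <- g <- numeric(length(q))
  for (x in ages) {
    dead <- ages < x
    f[x + 1] <- sum(d[dead]) / radix
    g[x + 1] <- sum(d[dead] * years_per_death[dead]) / T0
  }
  list(f = c(f, 1), g = c(g, 1), T0 = T0)
}

oracle_gini <- function(q, radix = 1e5) {
  lz <- oracle_lorenz(q, radix)
  omega <- length(q) - 1
  idx <- seq_len(omega)
  sum(lz$f[idx] - lz$g[idx]) / sum(lz$f[idx])
}
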