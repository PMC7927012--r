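## Two-way functional ANOVA by random projections.  Each curve is reduced
## to K scalars by projecting onto K random directions (standard Brownian
## motion on the grid); a classical balanced two-way ANOVA is run per
## direction; and the K p-values of each hypothesis are combined by the
## false-discovery-rate rule min_i K p_(i) / i.

#' Project curves onto random Brownian directions
#'
#' Directions are realizations of standard Brownian motion on the common
#' grid: cumulative sums of iid `N(0, 1/H)` increments.  The projection is
#' the plain dot product on the grid; the same `K` directions are applied
#' to every curve (directions are not normalized: the downstream F
#' statistics are scale-invariant per direction).
#'
#' @param curves Matrix of curves, one per row, on a common `H`-point grid.
#' @param K Number of projections.
#' @param seed Optional integer seed for the directions.
#' @param directions Optional pre-drawn `H x K` direction matrix (used to
#'   share directions across related tests).
#' @return List with `scores` (curves x K) and `directions` (H x K).
#' @export
project_curves <- function(curves, K = 30, seed = NULL, directions = NULL) {
  curves <- as.matrix(curves)
  H <- ncol(curves)
  if (is.null(directions)) {
    stopifnot_scalar_count(K, "K")
    if (!is.null(seed)) set.seed(seed)
    directions <- apply(matrix(stats::rnorm(H * K, sd = 1 / sqrt(H)), H, K),
                        2, cumsum)
    if (H == 1) directions <- matrix(directions, 1, K)
  } else {
    directions <- as.matrix(directions)
    if (nrow(directions) != H) stop("direction grid does not match the curves")
  }
  list(scores = curves %*% directions, directions = directions)
}

#' Balanced two-way fixed-effects ANOVA
#'
#' Standard decomposition for a balanced design with interaction, fitted
#' with `stats::lm`; p-values from the F distribution.  If the response is
#' exactly constant (no within-cell variance and no effects) all three
#' p-values are 1 by convention.
#'
#' @param y Numeric response vector.
#' @param factorA,factorB Factors of equal length (balanced design).
#' @return List with `p` (named p-values for A, B, A:B), `F` statistics
#'   and the `anova` table.
#' @export
two_way_anova <- function(y, factorA, factorB) {
  factorA <- as.factor(factorA); factorB <- as.factor(factorB)
  if (length(unique(table(factorA, factorB))) != 1) {
    stop("design must be balanced")
  }
  if (stats::sd(y) < 1e-300 * max(1, abs(mean(y)))) {
    p <- c(A = 1, B = 1, AB = 1)
    return(list(p = p, F = c(A = 0, B = 0, AB = 0), table = NULL))
  }
  tab <- stats::anova(stats::lm(y ~ factorA * factorB))
  Fv <- tab$`F value`[1:3]
  pv <- tab$`Pr(>F)`[1:3]
  pv[is.na(pv)] <- 1
  names(Fv) <- names(pv) <- c("A", "B", "AB")
  list(p = pv, F = Fv, table = tab)
}

#' Combine projection p-values by the false-discovery-rate rule
#'
#' With order statistics `p_(1) <= ... <= p_(K)`, returns
#' `min(1, min_i K p_(i) / i)`.
#'
#' @param pvals Vector of `K` p-values in `[0, 1]`.
#' @return Combined p-value.
#' @export
fdr_combine <- function(pvals) {
  if (length(pvals) == 0) stop("need at least one p-value")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  ps <- sort(pvals)
  K <- length(ps)
  min(1, min(K * ps / seq_len(K)))
}

## flatten a curve set to a (9N x H) matrix plus factor labels
flatten_curveset <- function(curveset) {
  stopifnot(inherits(curveset, "indicator_curve_set"))
  d <- dim(curveset$curves)
  lev_m <- dimnames(curveset$curves)[[1]] %||% paste0("M", seq_len(d[1]))
  lev_s <- dimnames(curveset$curves)[[2]] %||% paste0("S", seq_len(d[2]))
  idx <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), n = seq_len(d[3]))
  curves <- t(vapply(seq_len(nrow(idx)), function(row) {
    curveset$curves[idx$i[row], idx$j[row], idx$n[row], ]
  }, numeric(d[4])))
  list(curves = curves,
       model = factor(lev_m[idx$i], levels = lev_m),
       sample = factor(lev_s[idx$j], levels = lev_s))
}

#' Random-projection functional ANOVA of an indicator curve set
#'
#' Tests the null hypotheses of no model effect, no sample (residual
#' source) effect and no interaction on the replicate indicator curves of
#' a balanced crossed design: each curve is projected onto `K` random
#' Brownian directions, a balanced two-way ANOVA is run per direction,
#' and each hypothesis' `K` p-values are combined by [fdr_combine()].
#'
#' @param curveset An `indicator_curve_set` (balanced, `N >= 2`).
#' @param K Number of random projections (default 30).
#' @param alpha Test level for the reported decisions.
#' @param seed Optional seed for the directions.
#' @param directions Optional pre-drawn directions (H x K).
#' @return Object of class `fanova_result`: combined `p_model`,
#'   `p_sample`, `p_interaction`, reject/non-reject `decisions`, the
#'   per-projection p-value matrix, `K`, `alpha` and the directions used.
#' @export
fanova_test <- function(curveset, K = 30, alpha = 0.05, seed = NULL,
                        directions = NULL) {
  fl <- flatten_curveset(curveset)
  if (curveset$N < 2) stop("need at least 2 replicates per cell")
  pr <- project_curves(fl$curves, K = K, seed = seed, directions = directions)
  K <- ncol(pr$scores)
  praw <- matrix(NA_real_, K, 3, dimnames = list(NULL, c("model", "sample",
                                                         "interaction")))
  for (k in seq_len(K)) {
    praw[k, ] <- two_way_anova(pr$scores[, k], fl$model, fl$sample)$p
  }
  p <- apply(praw, 2, fdr_combine)
  structure(
    list(p_model = p[["model"]], p_sample = p[["sample"]],
         p_interaction = p[["interaction"]],
         decisions = ifelse(p < alpha, "R", "NR"),
         p_projections = praw, K = K, alpha = alpha,
         directions = pr$directions, indicator = curveset$indicator),
    class = "fanova_result"
  )
}

#' @export
print.fanova_result <- function(x, ...) {
  cat(sprintf("Functional ANOVA (%s), K = %d, alpha = %g\n", x$indicator,
              x$K, x$alpha))
  cat(sprintf("  model:       p = %.4g [%s]\n", x$p_model, x$decisions[1]))
  cat(sprintf("  sample:      p = %.4g [%s]\n", x$p_sample, x$decisions[2]))
  cat(sprintf("  interaction: p = %.4g [%s]\n", x$p_interaction,
              x$decisions[3]))
  invisible(x)
}

#' Pairwise level comparisons for one factor of the design
#'
#' For every pair of levels of the chosen factor, restricts the curves to
#' the two levels, pools over the other factor, runs a one-way ANOVA per
#' random projection and combines by [fdr_combine()].  Both the raw
#' combined p and its Benjamini-Hochberg adjustment across the pairs are
#' reported; the default decision uses the raw p at `alpha`.
#'
#' @inheritParams fanova_test
#' @param factor_name `"model"` or `"sample"`.
#' @return Data frame with one row per pair: `level1`, `level2`, `p`,
#'   `p_adjusted`, `decision`.
#' @export
pairwise_comparisons <- function(curveset, factor_name = c("model", "sample"),
                                 K = 30, alpha = 0.05, seed = NULL,
                                 directions = NULL) {
  factor_name <- match.arg(factor_name)
  fl <- flatten_curveset(curveset)
  f <- fl[[factor_name]]
  levs <- levels(f)
  if (length(levs) < 2) stop("factor needs at least 2 levels")
  pr <- project_curves(fl$curves, K = K, seed = seed, directions = directions)
  K <- ncol(pr$scores)
  pairs <- utils::combn(levs, 2)
  praw <- numeric(ncol(pairs))
  for (pidx in seq_len(ncol(pairs))) {
    keep <- f %in% pairs[, pidx]
    fk <- droplevels(f[keep])
    pk <- vapply(seq_len(K), function(k) {
      y <- pr$scores[keep, k]
      if (stats::sd(y) < 1e-300 * max(1, abs(mean(y)))) return(1)
      tab <- stats::anova(stats::lm(y ~ fk))
      p <- tab$`Pr(>F)`[1]
      if (is.na(p)) 1 else p
    }, numeric(1))
    praw[pidx] <- fdr_combine(pk)
  }
  padj <- stats::p.adjust(praw, method = "BH")
  data.frame(level1 = pairs[1, ], level2 = pairs[2, ], p = praw,
             p_adjusted = padj,
             decision = ifelse(praw < alpha, "R", "NR"),
             stringsAsFactors = FALSE)
}
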