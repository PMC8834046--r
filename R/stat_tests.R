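# Two-sided comparison statistics used throughout the score analyses.
# These are thin, contract-enforcing wrappers over the standard R
# implementations; all return `htest` objects so the usual print method
# applies.

#' Pearson correlation with significance test
#'
#' Product-moment correlation with a two-sided p-value from the
#' t-transform on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return An \code{htest} with \code{estimate} (r) and \code{p.value}.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_ginscore("x and y must have equal length")
  if (length(x) < 3) stop_ginscore("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_ginscore("correlation undefined for constant input")
  }
  stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
}

#' Unpaired two-group rank test (Mann-Whitney U)
#'
#' Exact two-sided p by enumeration for small tie-free samples
#' (combined n <= \code{exact_limit}); otherwise the normal approximation
#' with tie and continuity correction.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param exact_limit Combined sample size at or below which the exact
#'   distribution is used when there are no ties.
#' @return An \code{htest}; the statistic is the U count for \code{x}.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 12) {
  if (length(x) == 0 || length(y) == 0) stop_ginscore("empty group")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y) <= exact_limit) && !ties
  stats::wilcox.test(x, y,
    alternative = "two.sided",
    exact = use_exact, correct = TRUE
  )
}

#' Kruskal-Wallis rank test for two or more groups
#'
#' Tie-corrected H statistic referred to a chi-square distribution with
#' k - 1 degrees of freedom. When every value is identical the statistic is
#' reported as 0 with p = 1 (by convention, rather than an error).
#'
#' @param groups List of non-empty numeric vectors (>= 2 groups, total
#'   n >= 3).
#' @return An \code{htest}.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop_ginscore("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0)) stop_ginscore("empty group")
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3) stop_ginscore("need total n >= 3")
  if (max(values) == min(values)) {
    return(structure(
      list(
        statistic = c(`Kruskal-Wallis chi-squared` = 0),
        parameter = c(df = length(groups) - 1),
        p.value = 1,
        method = "Kruskal-Wallis rank sum test (degenerate: all values equal)",
        data.name = "groups"
      ),
      class = "htest"
    ))
  }
  stats::kruskal.test(groups)
}

#' Paired two-group rank test (Wilcoxon signed-rank)
#'
#' The paired analogue of the Mann-Whitney test. Zero differences are
#' dropped before ranking (Wilcoxon's original rule; count reported via
#' \code{message}). For n <= \code{exact_limit} non-zero differences the
#' two-sided p is exact, by enumeration of all 2^n sign patterns
#' conditional on the observed magnitudes (so tied magnitudes are handled
#' exactly too); larger samples use the normal approximation with tie and
#' continuity correction. The reported statistic W is the smaller of the
#' two signed-rank sums.
#'
#' @param x,y Paired numeric vectors of equal length with at least one
#'   non-zero difference.
#' @param exact_limit Number of non-zero differences at or below which the
#'   exact enumeration is used.
#' @return An \code{htest}.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 15) {
  if (length(x) != length(y)) stop_ginscore("x and y must have equal length")
  d <- x - y
  zero <- d == 0
  if (all(zero)) stop_ginscore("all paired differences are zero")
  if (any(zero)) {
    message("wilcoxon_signed_rank: dropped ", sum(zero), " zero difference(s)")
    d <- d[!zero]
  }
  n <- length(d)
  ar <- rank(abs(d))
  v_plus <- sum(ar[d > 0])
  if (n <= exact_limit) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.vector(signs %*% ar)
    p <- min(1, 2 * min(mean(v_all <= v_plus), mean(v_all >= v_plus)))
    method <- "Wilcoxon signed rank test (exact sign-pattern enumeration)"
  } else {
    p <- stats::wilcox.test(d,
      alternative = "two.sided", mu = 0,
      exact = FALSE, correct = TRUE
    )$p.value
    method <- "Wilcoxon signed rank test (normal approximation)"
  }
  structure(
    list(
      statistic = c(W = min(v_plus, n * (n + 1) / 2 - v_plus)),
      p.value = p,
      method = method,
      data.name = "paired differences",
      n = n
    ),
    class = "htest"
  )
}

#' Friedman rank test for complete blocks
#'
#' Within-subject ranks across conditions, tie-corrected chi-square
#' statistic with k - 1 degrees of freedom.
#'
#' @param blocks Numeric matrix, subjects in rows, conditions in columns
#'   (>= 2 of each); blocks must be complete (no missing values).
#' @return An \code{htest}.
#' @export
friedman_test <- function(blocks) {
  blocks <- as.matrix(blocks)
  if (nrow(blocks) < 2 || ncol(blocks) < 2) {
    stop_ginscore("need >= 2 subjects and >= 2 conditions")
  }
  if (any(!is.finite(blocks))) stop_ginscore("incomplete block: missing values")
  stats::friedman.test(blocks)
}
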