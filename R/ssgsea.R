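# Single-sample gene-set enrichment (the GIN score).
#
# Classic single-sample GSEA statistic: per sample, genes are rank-
# normalized; the enrichment score is the integrated difference between the
# weighted empirical CDF of the set genes (weights rank^alpha) and the
# uniform ECDF of the remaining genes, accumulated walking the genes from
# highest to lowest expression.

#' Rank-normalize one sample's expression values
#'
#' Ascending ranks (1 = lowest expression, N = highest), ties averaged.
#' Ranks are invariant under any strictly increasing transform of the
#' values, which is what makes the downstream score normalization-agnostic.
#'
#' @param expr_column Named numeric vector of per-gene expression values.
#' @return Named numeric vector of ranks.
#' @export
rank_normalize_sample <- function(expr_column) {
  if (length(expr_column) < 2) stop_ginscore("need at least 2 genes to rank")
  if (is.null(names(expr_column))) stop_ginscore("expression values must be named by gene")
  if (any(!is.finite(expr_column))) stop_ginscore("non-finite expression values")
  if (max(expr_column) == min(expr_column)) {
    stop_ginscore("all expression values identical; ranking is degenerate")
  }
  rank(expr_column, ties.method = "average")
}

#' Enrichment score of a gene set in one ranked sample
#'
#' Walks the genes in decreasing rank order (ties broken by gene id for
#' determinism). At each in-set gene the in-set cumulative weight advances
#' by \code{rank^alpha} (normalized to total 1 over the set); at each
#' out-of-set gene the out-of-set ECDF advances by \code{1/(N - m)}. The
#' score is the sum over all N positions of the difference of the two
#' cumulative curves - an integrated ECDF difference, not the max-deviation
#' statistic of two-group GSEA.
#'
#' @param ranked Named numeric vector of ranks from [rank_normalize_sample()].
#' @param set A [gene_set()] or character vector of gene ids.
#' @param alpha Rank-weighting exponent; 0.25 is the conventional default,
#'   0 gives the unweighted ECDF difference.
#' @return Unitless enrichment score.
#' @export
enrichment_score_sample <- function(ranked, set, alpha = 0.25) {
  genes <- if (inherits(set, "gene_set")) set$genes else as.character(set)
  n <- length(ranked)
  present <- intersect(genes, names(ranked))
  m <- length(present)
  if (m == 0) stop_ginscore("no gene of the set is present among ranked genes")
  if (m == n) stop_ginscore("gene set covers the whole universe; no complement")
  ord <- order(-ranked, names(ranked), method = "radix")
  in_set <- names(ranked)[ord] %in% present
  w_in <- numeric(n)
  rw <- ranked[ord][in_set]^alpha
  w_in[in_set] <- rw / sum(rw)
  step_out <- (!in_set) / (n - m)
  sum(cumsum(w_in) - cumsum(step_out))
}

#' Score every sample of a matrix for one gene set
#'
#' Computes the single-sample enrichment score of \code{set} in each column
#' of \code{expr}. Because scoring only uses within-sample ranks, any
#' per-sample strictly monotone transform of the data leaves the scores
#' unchanged, and (unless \code{normalize}) each sample's score is
#' independent of which other samples are present.
#'
#' @param expr Expression matrix (genes x samples).
#' @param set A [gene_set()] or character vector. At least half of the set
#'   must be present among the matrix genes.
#' @param alpha Rank-weighting exponent (default 0.25).
#' @param normalize Divide all scores by their range (max - min) across the
#'   samples of this matrix. Off by default: it ties a sample's score to
#'   the cohort it was scored with.
#' @param min_overlap Minimum fraction of the set that must be present.
#' @return A \code{score_table}: data frame with columns \code{sample_id},
#'   \code{gene_set}, \code{score}; attributes \code{alpha},
#'   \code{normalized}.
#' @export
score_matrix <- function(expr, set, alpha = 0.25, normalize = FALSE,
                         min_overlap = 0.5) {
  stopifnot(is.matrix(expr))
  present <- check_set_overlap(set, rownames(expr), floor = min_overlap)
  set_name <- if (inherits(set, "gene_set")) set$name else "gene_set"
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    col <- expr[, j]
    names(col) <- rownames(expr)
    enrichment_score_sample(rank_normalize_sample(col), present, alpha)
  }, numeric(1))
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng == 0) stop_ginscore("cannot range-normalize: all scores identical")
    scores <- scores / rng
  }
  structure(
    data.frame(
      sample_id = colnames(expr), gene_set = set_name, score = scores,
      stringsAsFactors = FALSE, row.names = NULL
    ),
    class = c("score_table", "data.frame"),
    alpha = alpha, normalized = normalize
  )
}

#' Extract scores as a named vector
#'
#' @param score_table A \code{score_table} from [score_matrix()].
#' @return Named numeric vector (names = sample ids).
#' @export
score_vector <- function(score_table) {
  out <- score_table$score
  names(out) <- score_table$sample_id
  out
}
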