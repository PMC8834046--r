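# Derivation of the genomic-instability gene signature: per-cohort
# expression-FGA Pearson correlations, a threshold sweep, and the
# dual-cohort intersection that defines the signature.

as_fga_vector <- function(fga) {
  if (is.data.frame(fga)) {
    stopifnot(all(c("sample_id", "fga") %in% names(fga)))
    out <- fga$fga
    names(out) <- fga$sample_id
    return(out)
  }
  if (is.numeric(fga) && !is.null(names(fga))) {
    return(fga)
  }
  stop_ginscore("fga must be a named numeric vector or a data frame with sample_id, fga")
}

#' Correlate every gene's expression with FGA in one cohort
#'
#' Computes, for each gene, the Pearson correlation between its expression
#' across samples and the per-sample fraction of genome altered. Samples are
#' matched by id between the matrix and the FGA vector; non-overlapping
#' samples are dropped with a message. Genes with zero expression variance
#' cannot be correlated and are excluded (reported via \code{message}).
#'
#' @param expr Expression matrix (genes x samples) as from
#'   [read_expression_table()].
#' @param fga Named numeric vector of FGA fractions, or a data frame with
#'   columns \code{sample_id} and \code{fga} as from [fga_table()].
#' @param cohort_id Label for the cohort (kept as an attribute).
#' @return A \code{correlation_table}: data frame with columns \code{gene}
#'   and \code{r}, attributes \code{cohort_id} and \code{n_samples}.
#' @export
compute_gene_fga_correlations <- function(expr, fga, cohort_id) {
  stopifnot(is.matrix(expr))
  fga <- as_fga_vector(fga)
  common <- intersect(colnames(expr), names(fga))
  dropped <- (ncol(expr) - length(common)) + (length(fga) - length(common))
  if (dropped > 0) {
    message(
      "compute_gene_fga_correlations[", cohort_id, "]: ", dropped,
      " sample(s) without expression/FGA pairing dropped"
    )
  }
  if (length(common) < 3) {
    stop_ginscore("fewer than 3 overlapping samples between expression and FGA")
  }
  x <- expr[, common, drop = FALSE]
  f <- fga[common]
  if (stats::sd(f) == 0) stop_ginscore("FGA is constant across samples")
  sds <- apply(x, 1, stats::sd)
  constant <- sds == 0
  if (all(constant)) stop_ginscore("all genes have constant expression")
  if (any(constant)) {
    message(
      "compute_gene_fga_correlations[", cohort_id, "]: excluded ",
      sum(constant), " constant gene(s)"
    )
    x <- x[!constant, , drop = FALSE]
  }
  r <- as.vector(stats::cor(t(x), f))
  out <- data.frame(gene = rownames(x), r = r, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out,
    class = c("correlation_table", "data.frame"),
    cohort_id = cohort_id, n_samples = length(common)
  )
}

#' Build a correlation table from precomputed values
#'
#' Convenience constructor for feeding externally published per-gene
#' correlations (or any precomputed values) into the selection machinery.
#'
#' @param genes Character vector of gene ids.
#' @param r Numeric vector of Pearson correlations in [-1, 1].
#' @param cohort_id Cohort label.
#' @param n_samples Number of samples the correlations were computed on.
#' @return A \code{correlation_table}.
#' @export
correlation_table <- function(genes, r, cohort_id, n_samples = NA_integer_) {
  stopifnot(length(genes) == length(r), !anyDuplicated(genes))
  if (any(!is.finite(r)) || any(abs(r) > 1)) {
    stop_ginscore("correlations must be finite and within [-1, 1]")
  }
  structure(
    data.frame(gene = as.character(genes), r = as.numeric(r), stringsAsFactors = FALSE),
    class = c("correlation_table", "data.frame"),
    cohort_id = cohort_id, n_samples = n_samples
  )
}

.passing_genes <- function(table, threshold, absolute = FALSE) {
  r <- if (absolute) abs(table$r) else table$r
  table$gene[r >= threshold]
}

#' Sweep correlation thresholds over two cohorts
#'
#' For each threshold, counts the genes whose correlation passes it in
#' \emph{both} cohorts (positive correlations only, unless
#' \code{absolute = TRUE}). Used to pick a threshold yielding a signature of
#' workable size (circa 10 to 50 genes).
#'
#' @param tableA,tableB \code{correlation_table} objects for the two cohorts.
#' @param grid Strictly increasing thresholds; default
#'   \code{c(0.2, 0.3, 0.35, 0.4)}.
#' @param absolute Pass genes on \code{|r|} rather than signed r.
#' @return Named integer vector: overlap count per threshold.
#' @export
sweep_thresholds <- function(tableA, tableB, grid = c(0.2, 0.3, 0.35, 0.4),
                             absolute = FALSE) {
  if (length(grid) == 0 || any(diff(grid) <= 0)) {
    stop_ginscore("grid must be non-empty and strictly increasing")
  }
  counts <- vapply(grid, function(t) {
    length(intersect(
      .passing_genes(tableA, t, absolute),
      .passing_genes(tableB, t, absolute)
    ))
  }, integer(1))
  names(counts) <- format(grid, trim = TRUE)
  counts
}

#' Select the dual-cohort signature at a correlation threshold
#'
#' The signature is the set of genes whose expression-FGA Pearson
#' correlation reaches \code{threshold} in both cohorts. Only positive
#' correlations are eligible by default (the published selection rule is
#' one-sided, r >= t); set \code{absolute = TRUE} to pass on magnitude. A
#' threshold sweep over \code{grid} is recorded in the result as an audit
#' trail, and a warning (not an error) is raised when the selected size
#' falls outside \code{size_window}.
#'
#' @inheritParams sweep_thresholds
#' @param threshold Correlation cutoff in (0, 1); default 0.35.
#' @param size_window Length-2 numeric: the intended signature size range.
#' @return Object of class \code{signature_selection} with elements
#'   \code{threshold}, \code{genes} (a [gene_set()]), \code{sweep},
#'   \code{cohorts}.
#' @examples
#' t1 <- gin_training_correlations()
#' a <- correlation_table(t1$symbol, t1$cor_ccle, "ccle", 32)
#' b <- correlation_table(t1$symbol, t1$cor_tcga, "tcga", 520)
#' sel <- select_signature(a, b, threshold = 0.35)
#' length(sel$genes$genes) # 20
#' @export
select_signature <- function(tableA, tableB, threshold = 0.35,
                             size_window = c(10, 50),
                             grid = c(0.2, 0.3, 0.35, 0.4),
                             absolute = FALSE) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop_ginscore("threshold must lie in (0, 1)")
  }
  selected <- sort(intersect(
    .passing_genes(tableA, threshold, absolute),
    .passing_genes(tableB, threshold, absolute)
  ))
  if (length(selected) == 0) {
    stop_ginscore(
      "no gene passes r >= ", threshold,
      " in both cohorts; try a lower threshold"
    )
  }
  if (length(selected) < size_window[1] || length(selected) > size_window[2]) {
    warning(
      "signature size ", length(selected), " outside the intended window [",
      size_window[1], ", ", size_window[2], "]",
      call. = FALSE
    )
  }
  sweep_grid <- sort(unique(c(grid, threshold)))
  cohorts <- c(
    attr(tableA, "cohort_id") %||% "cohortA",
    attr(tableB, "cohort_id") %||% "cohortB"
  )
  structure(
    list(
      threshold = threshold,
      genes = gene_set(
        name = sprintf("GIN_r%g", threshold),
        description = paste0(
          "genes with expression-FGA r >= ", threshold, " in ",
          cohorts[1], " and ", cohorts[2]
        ),
        genes = selected
      ),
      sweep = sweep_thresholds(tableA, tableB, sweep_grid, absolute),
      cohorts = cohorts
    ),
    class = "signature_selection"
  )
}

#' @export
print.signature_selection <- function(x, ...) {
  cat(
    "signature_selection: ", length(x$genes$genes), " genes at r >= ",
    x$threshold, " in both ", x$cohorts[1], " and ", x$cohorts[2], "\n",
    sep = ""
  )
  cat("threshold sweep (overlap counts):\n")
  print(x$sweep)
  invisible(x)
}
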