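# Expression-matrix and gene-set (GMT) I/O.

#' Read a gene-by-sample expression table
#'
#' Expects a tab-separated file with gene identifiers in the first column
#' and one column per sample, header row required. Values are assumed to be
#' already normalized (typically log-scale); no transformation is applied.
#' Rows containing any non-finite value are dropped (count reported via
#' \code{message}); duplicated gene identifiers are resolved by keeping the
#' row with the highest mean expression.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, genes in rows (rownames), samples in columns
#'   (colnames), column order as in the file.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop_ginscore("expression file not found: ", path)
  tab <- utils::read.delim(path,
    header = TRUE, sep = "\t",
    check.names = FALSE, stringsAsFactors = FALSE
  )
  if (ncol(tab) < 2) stop_ginscore("expression table needs >= 1 sample column")
  samples <- names(tab)[-1]
  if (anyDuplicated(samples)) {
    stop_ginscore(
      "duplicate sample ids: ",
      paste(unique(samples[duplicated(samples)]), collapse = ", ")
    )
  }
  genes <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  keep <- apply(is.finite(mat), 1, all)
  if (any(!keep)) {
    message(
      "read_expression_table: dropped ", sum(!keep),
      " row(s) with non-finite values"
    )
    mat <- mat[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  if (anyDuplicated(genes)) {
    dup_ids <- unique(genes[duplicated(genes)])
    message(
      "read_expression_table: resolved ", length(dup_ids),
      " duplicated gene id(s) by keeping the row with highest mean"
    )
    means <- rowMeans(mat)
    keep_row <- rep(TRUE, length(genes))
    for (g in dup_ids) {
      rows <- which(genes == g)
      keep_row[rows] <- FALSE
      keep_row[rows[which.max(means[rows])]] <- TRUE
    }
    mat <- mat[keep_row, , drop = FALSE]
    genes <- genes[keep_row]
  }
  if (nrow(mat) == 0) stop_ginscore("no rows left after filtering: ", path)
  rownames(mat) <- genes
  colnames(mat) <- samples
  mat
}

#' Write an expression matrix as TSV
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_expression_table <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  out <- data.frame(
    gene_id = rownames(mat), mat,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(out, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Construct a gene set
#'
#' @param name Set name.
#' @param description Free-text description.
#' @param genes Character vector of gene symbols; duplicates are removed
#'   with a warning.
#' @return Object of class \code{gene_set}.
#' @export
gene_set <- function(name, description = "", genes = character(0)) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  genes <- as.character(genes)
  if (length(genes) == 0) stop_ginscore("gene set '", name, "' is empty")
  if (anyDuplicated(genes)) {
    warning("gene set '", name, "': duplicated genes removed", call. = FALSE)
    genes <- unique(genes)
  }
  structure(
    list(name = name, description = as.character(description), genes = genes),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set:", x$name, "(", length(x$genes), "genes )\n")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Broad-dialect GMT: one set per line, tab-separated fields
#' \code{name, description, gene1, gene2, ...}. Lines with fewer than three
#' fields raise a parse error naming the line.
#'
#' @param path Path to a GMT file.
#' @return Named list of [gene_set()] objects.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop_ginscore("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop_ginscore("GMT parse error on line ", i, ": fewer than 3 fields")
    }
    sets[[i]] <- gene_set(fields[1], fields[2], fields[-(1:2)])
  }
  names(sets) <- vapply(sets, function(s) s$name, character(1))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets List of [gene_set()] objects.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    stopifnot(inherits(s, "gene_set"))
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1))
  ok <- try(writeLines(lines, path), silent = TRUE)
  if (inherits(ok, "try-error")) stop_ginscore("cannot write GMT file: ", path)
  invisible(path)
}

#' The packaged 20-gene genomic-instability signature
#'
#' The 20 genes whose expression passed the Pearson r >= 0.35 filter against
#' the fraction of genome altered in both training cohorts (a TCGA head-and-
#' neck tumor cohort and a CCLE upper-aerodigestive cell-line panel). Ships
#' with the package as a GMT fixture.
#'
#' @return A [gene_set()] of 20 genes.
#' @export
gin_signature <- function() {
  path <- system.file("extdata", "gin20.gmt", package = "ginscore")
  read_gene_sets(path)[[1]]
}

#' Published per-gene correlations of the 20-gene signature
#'
#' The printed per-gene Pearson correlations of the signature genes with the
#' fraction of genome altered in the two training cohorts.
#'
#' @return Data frame with columns \code{symbol}, \code{cor_ccle},
#'   \code{cor_tcga}.
#' @export
gin_training_correlations <- function() {
  path <- system.file("extdata", "gin20_correlations.tsv", package = "ginscore")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# Overlap rule between a gene set and an expression universe: exact,
# case-sensitive symbol match; scoring requires at least `floor` of the set
# to be present.
check_set_overlap <- function(set, universe, floor = 0.5) {
  genes <- if (inherits(set, "gene_set")) set$genes else as.character(set)
  present <- intersect(genes, universe)
  missing <- setdiff(genes, universe)
  if (length(present) / length(genes) < floor) {
    stop_ginscore(
      "gene set overlap below ", floor * 100, "% of the set; missing: ",
      paste(missing, collapse = ", ")
    )
  }
  if (length(missing) > 0) {
    message(
      "gene set: ", length(missing), " gene(s) absent from matrix, ignored: ",
      paste(missing, collapse = ", ")
    )
  }
  present
}
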