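# Pipeline orchestration: derive -> score -> associate -> survive, from a
# single configuration, with a machine-readable report.

read_fga_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "fga") %in% names(tab))) {
    stop_ginscore("FGA table needs columns sample_id, fga: ", path)
  }
  stats::setNames(tab$fga, tab$sample_id)
}

# Load per-sample FGA for a cohort entry: either a precomputed `fga` TSV or
# a `seg` file to run compute_fga on.
.cohort_fga <- function(entry) {
  if (!is.null(entry$fga)) {
    return(read_fga_tsv(entry$fga))
  }
  if (!is.null(entry$seg)) {
    tab <- fga_table(
      read_seg(entry$seg),
      alteration_threshold = entry$alteration_threshold %||% 0.2,
      linear = isTRUE(entry$linear)
    )
    return(stats::setNames(tab$fga, tab$sample_id))
  }
  NULL
}

.check_files_exist <- function(config) {
  paths <- character(0)
  for (entry in c(list(config$cohort_a, config$cohort_b), config$validation)) {
    if (is.null(entry)) next
    paths <- c(paths, unlist(
      entry[intersect(names(entry), c("expr", "fga", "seg", "clinical"))]
    ))
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop_ginscore(
      "config validation: missing file(s): ", paste(missing, collapse = ", ")
    )
  }
  invisible(TRUE)
}

#' Run the full derive / score / validate / survive pipeline
#'
#' Stages, in order: (1) validate the configuration (all referenced files
#' must exist before any computation starts); (2) derive the signature from
#' the two training cohorts by dual-cohort correlation selection;
#' (3) score every validation cohort with the single-sample enrichment
#' statistic; (4) report the Pearson correlation between score and FGA in
#' each validation cohort that has FGA; (5) for cohorts with clinical
#' follow-up, find the maximally selected score cutpoint, compare high/low
#' groups by log-rank, and fit uni- and multivariate Cox models. Outputs
#' (\code{signature.gmt}, \code{sweep.tsv}, \code{scores_<cohort>.tsv},
#' \code{report.json}) are written to \code{out_dir}; any stage error
#' aborts the run, removes partial outputs, and names the failing stage.
#' File outputs contain no timestamps, so a rerun with the same inputs,
#' configuration and seed is byte-identical.
#'
#' @param config Nested list (or path to a YAML file with the same
#'   structure): \code{cohort_a} / \code{cohort_b} each with \code{expr}
#'   plus \code{fga} or \code{seg}; \code{validation} a named list of
#'   cohorts with \code{expr} and optional \code{fga}/\code{seg},
#'   \code{clinical} (TSV: sample_id, time, event, covariates) and
#'   \code{covariates} (character vector for the multivariate Cox model);
#'   optional scalars \code{threshold} (0.35), \code{grid}, \code{alpha}
#'   (0.25), \code{normalize} (FALSE), \code{minprop} (0.1),
#'   \code{n_perm} (1000), \code{seed}, \code{out_dir}.
#' @param verbose Emit per-stage progress messages.
#' @return Invisibly, the run report: a list with the signature, sweep,
#'   per-cohort correlation and survival results, and per-stage timings
#'   (timings are only in the returned object, never in files).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_ginscore("reading YAML configs requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  say <- function(...) if (verbose) message("[ginscore] ", ...)
  out_dir <- config$out_dir
  written <- character(0)
  ok <- FALSE
  on.exit({
    if (!ok && length(written) > 0) {
      unlink(written)
    }
  })
  emit <- function(writer, filename) {
    if (is.null(out_dir)) {
      return(invisible(NULL))
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(out_dir, filename)
    writer(path)
    written <<- c(written, path)
    path
  }
  timings <- list()
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(code), error = function(e) {
      stop_ginscore("stage '", name, "' failed: ", conditionMessage(e))
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    say("stage ", name, " done")
    res
  }

  stage("validate", .check_files_exist(config))
  if (is.null(config$cohort_a) || is.null(config$cohort_b)) {
    stop_ginscore("config needs cohort_a and cohort_b for derivation")
  }

  threshold <- config$threshold %||% 0.35
  grid <- config$grid %||% c(0.2, 0.3, 0.35, 0.4)
  alpha <- config$alpha %||% 0.25
  normalize <- isTRUE(config$normalize)
  seed <- config$seed %||% 1L

  selection <- stage("derive", {
    expr_a <- read_expression_table(config$cohort_a$expr)
    expr_b <- read_expression_table(config$cohort_b$expr)
    fga_a <- .cohort_fga(config$cohort_a)
    fga_b <- .cohort_fga(config$cohort_b)
    if (is.null(fga_a) || is.null(fga_b)) {
      stop_ginscore("training cohorts need fga or seg entries")
    }
    ta <- compute_gene_fga_correlations(
      expr_a, fga_a, config$cohort_a$id %||% "cohort_a"
    )
    tb <- compute_gene_fga_correlations(
      expr_b, fga_b, config$cohort_b$id %||% "cohort_b"
    )
    select_signature(ta, tb, threshold = threshold, grid = grid)
  })
  emit(function(p) write_gene_sets(list(selection$genes), p), "signature.gmt")
  emit(function(p) {
    utils::write.table(
      data.frame(
        threshold = names(selection$sweep),
        overlap = as.integer(selection$sweep)
      ),
      p,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }, "sweep.tsv")

  validation <- config$validation %||% list()
  if (length(validation) > 0 && is.null(names(validation))) {
    names(validation) <- sprintf("cohort%d", seq_along(validation))
  }
  cohort_reports <- list()
  for (nm in names(validation)) {
    entry <- validation[[nm]]
    rep_entry <- list()
    scores <- stage(paste0("score:", nm), {
      expr_v <- read_expression_table(entry$expr)
      score_vector(score_matrix(
        expr_v, selection$genes,
        alpha = alpha, normalize = normalize
      ))
    })
    emit(function(p) {
      utils::write.table(
        data.frame(
          sample_id = names(scores),
          gene_set = selection$genes$name, score = scores
        ),
        p,
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }, paste0("scores_", nm, ".tsv"))
    fga_v <- .cohort_fga(entry)
    if (!is.null(fga_v)) {
      rep_entry$fga_correlation <- stage(paste0("associate:", nm), {
        common <- intersect(names(scores), names(fga_v))
        ht <- pearson_r(scores[common], fga_v[common])
        list(
          r = unname(ht$estimate), p_value = ht$p.value,
          n = length(common)
        )
      })
    }
    if (!is.null(entry$clinical)) {
      rep_entry$survival <- stage(paste0("survive:", nm), {
        clin <- as_survival_table(
          utils::read.delim(entry$clinical, stringsAsFactors = FALSE)
        )
        ms <- maxstat_cutoff(
          scores, clin,
          minprop = config$minprop %||% 0.1,
          n_perm = config$n_perm %||% 1000,
          seed = seed
        )
        grp <- dichotomize_scores(scores[clin$sample_id], ms$cutoff)
        lr <- logrank_test(clin[grp == "high", ], clin[grp == "low", ])
        clin$gin_group <- grp
        covars <- intersect(entry$covariates %||% character(0), names(clin))
        uni <- cox_fit(clin, "gin_group")
        multi <- if (length(covars) > 0) {
          cox_fit(clin, c("gin_group", covars))
        }
        km_high <- km_estimate(clin[grp == "high", ])
        km_low <- km_estimate(clin[grp == "low", ])
        list(
          cutoff = ms$cutoff,
          maxstat_statistic = ms$statistic,
          maxstat_p = ms$p_value,
          n_high = sum(grp == "high"), n_low = sum(grp == "low"),
          logrank_p = lr$p.value,
          cox_univariate = list(
            hr = unname(uni$hazard_ratios["gin_grouphigh"]),
            ci95 = unname(uni$ci95["gin_grouphigh", ]),
            p = unname(uni$p_values["gin_grouphigh"])
          ),
          cox_multivariate = if (!is.null(multi)) {
            list(
              hr = unname(multi$hazard_ratios["gin_grouphigh"]),
              ci95 = unname(multi$ci95["gin_grouphigh", ]),
              p = unname(multi$p_values["gin_grouphigh"]),
              covariates = covars
            )
          },
          km = list(
            high = list(
              time = km_high$event_times, surv = km_high$survival_probs
            ),
            low = list(
              time = km_low$event_times, surv = km_low$survival_probs
            )
          )
        )
      })
    }
    cohort_reports[[nm]] <- rep_entry
  }

  report <- list(
    seed = seed,
    threshold = threshold,
    alpha = alpha,
    normalize = normalize,
    signature = selection$genes$genes,
    sweep = as.list(selection$sweep),
    cohorts = cohort_reports
  )
  emit(function(p) {
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA)
  }, "report.json")
  ok <- TRUE
  report$timings <- timings
  say("pipeline complete")
  invisible(report)
}
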