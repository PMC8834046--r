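# Synthetic cohorts with the statistical structure the pipeline assumes:
# segmented copy-number profiles with known FGA, an expression matrix with
# a planted FGA-coupled gene subset, and survival times whose hazard
# depends on the planted score.

# Toy genome: 22 autosome-like chromosomes, lengths proportional to the
# human autosomes, rescaled to a 3e9 bp total.
.toy_chrom_lengths <- local({
  mb <- c(
    248, 242, 198, 190, 181, 171, 159, 145, 138, 134, 135, 133,
    114, 107, 102, 90, 83, 80, 59, 64, 47, 51
  )
  len <- round(mb * 1e6 * (3e9 / sum(mb * 1e6)))
  names(len) <- as.character(1:22)
  len
})

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults emulate
#' the study conditions the pipeline is designed for: an OPMD-like cohort
#' of 86 samples followed ~10 years, FGA drawn from Beta(2, 3)
#' (mean 0.4, head-and-neck-scale instability), 25 planted genes whose
#' expression is linear in FGA with Gaussian noise calibrated to a
#' population correlation of 0.5, and a hazard that multiplies by 3.5 per
#' standard deviation of the planted score.
#'
#' @param n_samples Number of samples.
#' @param n_genes Total genes in the expression matrix.
#' @param n_planted Number of planted FGA-coupled genes (<= n_genes).
#' @param target_r Population Pearson correlation between a planted gene
#'   and FGA, in (0, 1).
#' @param fga_shape Length-2 Beta shape parameters for the target FGA
#'   distribution; \code{c(0, 1)} degenerates to FGA = 0 everywhere.
#' @param noise_sd Expression noise SD for planted genes; \code{NULL}
#'   derives it from \code{target_r} and the Beta SD.
#' @param segment_range Range of per-sample segment counts over the toy
#'   genome.
#' @param hazard_baseline Baseline hazard, events per month.
#' @param log_hr_per_sd Log hazard ratio per standard deviation of score.
#' @param censor_horizon Upper bound (months) of the uniform independent
#'   censoring time.
#' @param seed Integer seed; fixes the whole cohort.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 86, n_genes = 1000, n_planted = 25,
                       target_r = 0.5, fga_shape = c(2, 3), noise_sd = NULL,
                       segment_range = c(50, 200),
                       hazard_baseline = 0.006, log_hr_per_sd = log(3.5),
                       censor_horizon = 120, seed = 1L) {
  stopifnot(
    n_samples >= 1, n_genes >= 1, n_planted >= 0, n_planted <= n_genes,
    target_r > 0, target_r < 1,
    length(fga_shape) == 2, all(fga_shape >= 0),
    length(segment_range) == 2, segment_range[1] >= 22,
    segment_range[2] >= segment_range[1],
    hazard_baseline > 0, censor_horizon > 0
  )
  structure(
    list(
      n_samples = as.integer(n_samples),
      n_genes = as.integer(n_genes),
      n_planted = as.integer(n_planted),
      target_r = target_r,
      fga_shape = fga_shape,
      noise_sd = noise_sd,
      segment_range = as.integer(segment_range),
      hazard_baseline = hazard_baseline,
      log_hr_per_sd = log_hr_per_sd,
      censor_horizon = censor_horizon,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

.sim_sample_ids <- function(config) {
  sprintf("S%03d", seq_len(config$n_samples))
}

# Draw the per-sample target FGA; a zero first shape degenerates to 0.
.draw_target_fga <- function(config) {
  if (config$fga_shape[1] == 0) {
    return(rep(0, config$n_samples))
  }
  stats::rbeta(config$n_samples, config$fga_shape[1], config$fga_shape[2])
}

#' Simulate segmented copy-number profiles with known FGA
#'
#' Per sample: a target FGA is drawn from the configured Beta
#' distribution; the 22-chromosome toy genome (3e9 bp) is partitioned into
#' 50-200 segments at uniform breakpoints; segments are marked altered
#' (|log2 ratio| > 0.2, random sign, magnitude in [0.25, 1.5]) greedily in
#' decreasing length order until the altered fraction reaches the target,
#' so the achieved FGA matches the target to within one segment's length;
#' unaltered segments get ratios in (-0.15, 0.15). The \emph{achieved}
#' fraction is recorded as the truth, so [compute_fga()] reproduces it
#' exactly.
#'
#' @param config A [sim_config()].
#' @return List with \code{profiles} (named list of [segment_profile()])
#'   and \code{true_fga} (named numeric vector of achieved fractions; the
#'   Beta-drawn targets are attached as attribute \code{target_fga}).
#' @export
simulate_copy_number <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 11L, {
    ids <- .sim_sample_ids(config)
    targets <- .draw_target_fga(config)
    chrlen <- .toy_chrom_lengths
    total_len <- sum(chrlen)
    profiles <- vector("list", config$n_samples)
    true_fga <- numeric(config$n_samples)
    for (s in seq_len(config$n_samples)) {
      n_seg <- sample(seq(config$segment_range[1], config$segment_range[2]), 1)
      extra <- stats::rmultinom(1, n_seg - 22L, prob = chrlen)[, 1]
      per_chrom <- 1L + extra
      seg_list <- vector("list", 22)
      for (c_idx in seq_len(22)) {
        L <- chrlen[c_idx]
        k <- per_chrom[c_idx]
        breaks <- if (k > 1) sort(sample.int(L - 1, k - 1)) else integer(0)
        starts <- c(0, breaks)
        ends <- c(breaks, L)
        seg_list[[c_idx]] <- data.frame(
          chrom = names(chrlen)[c_idx], start = starts, end = ends,
          stringsAsFactors = FALSE
        )
      }
      seg <- do.call(rbind, seg_list)
      len <- seg$end - seg$start
      # greedy cover of the target altered length, largest segments first
      target_len <- targets[s] * total_len
      altered <- logical(nrow(seg))
      acc <- 0
      for (i in order(len, decreasing = TRUE)) {
        if (acc + len[i] <= target_len) {
          altered[i] <- TRUE
          acc <- acc + len[i]
        }
      }
      n_alt <- sum(altered)
      ratio <- stats::runif(nrow(seg), -0.15, 0.15)
      if (n_alt > 0) {
        ratio[altered] <- sample(c(-1, 1), n_alt, replace = TRUE) *
          stats::runif(n_alt, 0.25, 1.5)
      }
      seg$log2_ratio <- ratio
      profiles[[s]] <- segment_profile(ids[s], seg)
      true_fga[s] <- acc / total_len
    }
    names(profiles) <- ids
    names(true_fga) <- ids
    names(targets) <- ids
    # the Beta-drawn targets ride along so callers can audit the greedy fit
    attr(true_fga, "target_fga") <- targets
    list(profiles = profiles, true_fga = true_fga)
  })
}

#' Simulate an expression matrix with planted FGA-coupled genes
#'
#' Planted genes follow \code{5 + FGA + noise} with the noise SD chosen so
#' the population correlation with FGA equals \code{target_r} (given the
#' configured Beta SD of FGA); background genes are independent
#' Gaussian noise around the same baseline.
#'
#' @param true_fga Named numeric vector of per-sample FGA fractions.
#' @param config A [sim_config()].
#' @return List with \code{expr} (matrix genes x samples) and
#'   \code{planted_genes} (a [gene_set()], empty-set \code{NULL} when
#'   \code{n_planted} is 0).
#' @export
simulate_expression <- function(true_fga, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(true_fga)
  with_seed(config$seed + 23L, {
    a <- config$fga_shape[1]
    b <- config$fga_shape[2]
    sd_f <- if (a == 0) 0 else sqrt(a * b / ((a + b)^2 * (a + b + 1)))
    noise_sd <- config$noise_sd %||%
      (sd_f * sqrt(1 / config$target_r^2 - 1))
    planted_names <- if (config$n_planted > 0) {
      sprintf("PLANT%03d", seq_len(config$n_planted))
    } else {
      character(0)
    }
    bg_names <- sprintf("BG%05d", seq_len(config$n_genes - config$n_planted))
    expr <- matrix(
      stats::rnorm(config$n_genes * n, mean = 5, sd = 1),
      nrow = config$n_genes,
      dimnames = list(c(planted_names, bg_names), names(true_fga))
    )
    if (config$n_planted > 0) {
      planted <- matrix(
        rep(5 + true_fga, each = config$n_planted) +
          stats::rnorm(config$n_planted * n, sd = noise_sd),
        nrow = config$n_planted
      )
      expr[seq_len(config$n_planted), ] <- planted
    }
    planted_set <- if (config$n_planted > 0) {
      gene_set("PLANTED", "simulated FGA-coupled genes", planted_names)
    }
    list(expr = expr, planted_genes = planted_set)
  })
}

#' Simulate survival times with score-dependent hazard
#'
#' Event times are exponential with hazard
#' \code{hazard_baseline * exp(log_hr_per_sd * z)}, where z is the
#' standardized score; censoring is independent uniform on
#' (0, censor_horizon). A 3-level treatment arm and a 2-level histology
#' covariate (both independent of outcome) are attached, mimicking a
#' chemoprevention-trial design.
#'
#' @param scores Named numeric vector of per-sample scores.
#' @param config A [sim_config()].
#' @return A survival table (see [as_survival_table()]) with covariates
#'   \code{arm} and \code{histology}.
#' @export
simulate_survival <- function(scores, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(scores)
  with_seed(config$seed + 37L, {
    z <- if (stats::sd(scores) == 0) {
      rep(0, n)
    } else {
      (scores - mean(scores)) / stats::sd(scores)
    }
    hazard <- config$hazard_baseline * exp(config$log_hr_per_sd * z)
    t_event <- stats::rexp(n, rate = hazard)
    t_censor <- stats::runif(n, 0, config$censor_horizon)
    as_survival_table(data.frame(
      sample_id = names(scores),
      time = pmin(t_event, t_censor),
      event = as.integer(t_event <= t_censor),
      arm = sample(c("13cRA", "RP", "RP_BC"), n, replace = TRUE),
      histology = sample(c("hyperplasia", "dysplasia"), n, replace = TRUE),
      stringsAsFactors = FALSE
    ))
  })
}

#' Simulate a full cohort
#'
#' Composes the copy-number, expression and survival generators: the
#' planted genes are scored with the single-sample enrichment statistic
#' and that score drives the hazard. Optionally writes the cohort to disk
#' in the package's standard formats.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes
#'   \code{expr.tsv}, \code{segments.seg}, \code{clinical.tsv} and
#'   \code{truth.json} (planted genes, true FGA, config).
#' @param alpha Rank-weighting exponent used when scoring the planted set.
#' @return Object of class \code{simulated_cohort}: list with
#'   \code{profiles}, \code{expr}, \code{true_fga}, \code{planted_genes},
#'   \code{scores}, \code{survival}, \code{config}.
#' @export
simulate_cohort <- function(config, out_dir = NULL, alpha = 0.25) {
  stopifnot(inherits(config, "sim_config"))
  cn <- simulate_copy_number(config)
  ex <- simulate_expression(cn$true_fga, config)
  scores <- if (!is.null(ex$planted_genes)) {
    score_vector(score_matrix(ex$expr, ex$planted_genes, alpha = alpha))
  } else {
    stats::setNames(rep(0, config$n_samples), names(cn$true_fga))
  }
  surv <- simulate_survival(scores, config)
  cohort <- structure(
    list(
      profiles = cn$profiles,
      expr = ex$expr,
      true_fga = cn$true_fga,
      planted_genes = ex$planted_genes,
      scores = scores,
      survival = surv,
      config = config
    ),
    class = "simulated_cohort"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_expression_table(cohort$expr, file.path(out_dir, "expr.tsv"))
    write_seg(cohort$profiles, file.path(out_dir, "segments.seg"))
    utils::write.table(
      as.data.frame(surv),
      file.path(out_dir, "clinical.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    utils::write.table(
      data.frame(sample_id = names(cn$true_fga), fga = cn$true_fga),
      file.path(out_dir, "fga.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    truth <- list(
      planted_genes = if (!is.null(ex$planted_genes)) ex$planted_genes$genes else character(0),
      true_fga = as.list(cn$true_fga),
      config = unclass(config)
    )
    jsonlite::write_json(
      truth, file.path(out_dir, "truth.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  cohort
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(
    "simulated_cohort:", x$config$n_samples, "samples,",
    x$config$n_genes, "genes (", x$config$n_planted, "planted ),",
    sum(x$survival$event), "events\n"
  )
  invisible(x)
}
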