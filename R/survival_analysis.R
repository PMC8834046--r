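# Time-to-event machinery: Kaplan-Meier, log-rank, Cox proportional
# hazards (Efron ties), proportional-hazards diagnostics, and the
# maximally selected log-rank cutpoint used to dichotomize a continuous
# score (high vs low genomic instability).

#' Validate a survival table
#'
#' A survival table records one row per sample: \code{sample_id},
#' \code{time} (months, >= 0), \code{event} (1 = event observed, 0 =
#' censored) and optional covariate columns (e.g. treatment arm,
#' histological grade).
#'
#' @param df Data frame.
#' @return The validated data frame with class \code{survival_table}.
#' @export
as_survival_table <- function(df) {
  df <- as.data.frame(df)
  required <- c("sample_id", "time", "event")
  if (!all(required %in% names(df))) {
    stop_ginscore("survival table needs columns ", paste(required, collapse = ", "))
  }
  if (any(is.na(df$time)) || any(is.na(df$event))) {
    stop_ginscore("missing time or event values")
  }
  if (any(df$time < 0)) stop_ginscore("negative survival time")
  if (!all(df$event %in% c(0, 1))) stop_ginscore("event must be 0 or 1")
  if (anyDuplicated(df$sample_id)) stop_ginscore("duplicated sample ids")
  class(df) <- unique(c("survival_table", class(df)))
  df
}

#' Kaplan-Meier product-limit estimate
#'
#' @param surv A survival table (see [as_survival_table()]).
#' @return A \code{km_curve}: list with \code{event_times},
#'   \code{survival_probs}, \code{at_risk} and the underlying
#'   \code{survival::survfit} object in \code{fit}.
#' @export
km_estimate <- function(surv) {
  surv <- as_survival_table(surv)
  if (nrow(surv) < 1) stop_ginscore("empty survival table")
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    data = surv, conf.type = "log"
  )
  structure(
    list(
      event_times = fit$time,
      survival_probs = fit$surv,
      at_risk = fit$n.risk,
      fit = fit
    ),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat("km_curve over", length(x$event_times), "time points\n")
  print(utils::head(data.frame(
    time = x$event_times, at_risk = x$at_risk, surv = x$survival_probs
  ), 10))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Observed-versus-expected events across the shared risk sets; chi-square
#' statistic on 1 degree of freedom, two-sided.
#'
#' @param survA,survB Survival tables for the two groups.
#' @return An \code{htest}.
#' @export
logrank_test <- function(survA, survB) {
  survA <- as_survival_table(survA)
  survB <- as_survival_table(survB)
  if (nrow(survA) == 0 || nrow(survB) == 0) stop_ginscore("empty group")
  combined <- data.frame(
    time = c(survA$time, survB$time),
    event = c(survA$event, survB$event),
    group = rep(c("A", "B"), c(nrow(survA), nrow(survB)))
  )
  if (sum(combined$event) == 0) stop_ginscore("no events in either group")
  sd_fit <- survival::survdiff(
    survival::Surv(time, event) ~ group,
    data = combined
  )
  chisq <- unname(sd_fit$chisq)
  structure(
    list(
      statistic = c(`chi-squared` = chisq),
      parameter = c(df = 1),
      p.value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
      method = "Log-rank test",
      data.name = "survA vs survB"
    ),
    class = "htest"
  )
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron handling of tied event
#' times. Categorical covariates are expanded to reference-coded
#' indicators; confidence intervals and p-values are Wald-based, matching
#' the usual hazard-ratio (HR, 95% CI) reporting.
#'
#' @param surv Survival table including the covariate columns.
#' @param covariate_names Character vector naming covariate columns.
#' @return A \code{cox_fit}: list with \code{coefficients},
#'   \code{hazard_ratios}, \code{ci95} (matrix with columns lower/upper),
#'   \code{p_values}, \code{n_events} and the underlying
#'   \code{survival::coxph} fit.
#' @export
cox_fit <- function(surv, covariate_names) {
  surv <- as_survival_table(surv)
  if (sum(surv$event) < 1) stop_ginscore("no events; Cox model undefined")
  missing_cov <- setdiff(covariate_names, names(surv))
  if (length(missing_cov) > 0) {
    stop_ginscore("covariate(s) not found: ", paste(missing_cov, collapse = ", "))
  }
  for (cv in covariate_names) {
    col <- surv[[cv]]
    if (length(unique(col)) < 2) {
      stop_ginscore("covariate '", cv, "' is constant")
    }
    if (is.character(col)) surv[[cv]] <- factor(col)
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", covariate_names), collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = surv, ties = "efron")
  if (any(is.na(stats::coef(fit)))) {
    stop_ginscore(
      "Cox fit failed to estimate: ",
      paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", ")
    )
  }
  s <- summary(fit)
  ci <- cbind(
    lower = s$conf.int[, "lower .95"],
    upper = s$conf.int[, "upper .95"]
  )
  rownames(ci) <- rownames(s$conf.int)
  structure(
    list(
      coefficients = stats::coef(fit),
      hazard_ratios = exp(stats::coef(fit)),
      ci95 = ci,
      p_values = s$coefficients[, "Pr(>|z|)"],
      n_events = fit$nevent,
      fit = fit
    ),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  tab <- data.frame(
    HR = x$hazard_ratios,
    lower95 = x$ci95[, "lower"],
    upper95 = x$ci95[, "upper"],
    p = x$p_values
  )
  cat("Cox proportional-hazards fit (Efron ties),", x$n_events, "events\n")
  print(round(tab, 4))
  invisible(x)
}

#' Proportional-hazards diagnostic per covariate
#'
#' Tests, for each fitted covariate, the association of the scaled
#' Schoenfeld residuals with (Kaplan-Meier transformed) time - a
#' time-varying coefficient indicates violation of proportionality.
#'
#' @param fit A [cox_fit()] result (or a \code{survival::coxph} fit).
#' @return Data frame with one row per covariate: \code{covariate},
#'   \code{chisq}, \code{df}, \code{p_value}.
#' @export
ph_assumption_check <- function(fit) {
  coxph_fit <- if (inherits(fit, "cox_fit")) fit$fit else fit
  stopifnot(inherits(coxph_fit, "coxph"))
  if (coxph_fit$nevent < 2) stop_ginscore("need at least 2 events")
  z <- survival::cox.zph(coxph_fit, transform = "km", global = FALSE)
  tab <- as.data.frame(z$table)
  data.frame(
    covariate = rownames(tab),
    chisq = tab$chisq,
    df = tab$df,
    p_value = tab$p,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

# Log-rank scores: a_i = event_i - NelsonAalen(time_i). A linear rank
# statistic in these scores over a binary split is the (permutation-
# standardized) log-rank statistic used by maximally selected rank
# statistics.
logrank_scores <- function(time, event) {
  n <- length(time)
  o <- order(time)
  t_s <- time[o]
  e_s <- event[o]
  cumhaz <- numeric(n)
  cum <- 0
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && t_s[j + 1] == t_s[i]) j <- j + 1
    d <- sum(e_s[i:j])
    at_risk <- n - i + 1
    if (d > 0) cum <- cum + d / at_risk
    cumhaz[i:j] <- cum
    i <- j + 1
  }
  a <- numeric(n)
  a[o] <- e_s - cumhaz
  a
}

# Standardized statistics for all candidate split positions k (low group =
# first k samples in score order), given scores `a` already in score order.
standardized_split_stats <- function(a_ordered, ks) {
  n <- length(a_ordered)
  abar <- mean(a_ordered)
  ssa <- sum((a_ordered - abar)^2)
  cs <- cumsum(a_ordered)
  m_high <- n - ks
  s_high <- sum(a_ordered) - cs[ks]
  e_high <- m_high * abar
  v_high <- m_high * (n - m_high) / (n * (n - 1)) * ssa
  (s_high - e_high) / sqrt(v_high)
}

#' Maximally selected log-rank cutpoint
#'
#' Scans candidate cutpoints (midpoints between consecutive distinct score
#' values whose induced high/low groups both contain at least
#' \code{minprop} of the samples) and, at each, computes the standardized
#' log-rank statistic of the high-versus-low split, using log-rank scores
#' (event indicator minus Nelson-Aalen cumulative hazard) with the exact
#' permutation mean and variance of the resulting linear rank statistic.
#' The cutoff is the argmax of the absolute statistic (ties resolved to
#' the lower cutoff). Significance is assessed by a seeded permutation
#' null of the maximal statistic, which accounts for the cutpoint
#' optimization, rather than by an asymptotic approximation.
#'
#' @param scores Named numeric vector of per-sample scores.
#' @param surv Survival table aligned to \code{scores} by \code{sample_id}.
#' @param minprop Minimum fraction of samples in each group, in (0, 0.5).
#' @param n_perm Number of label permutations for the p-value; 0 skips the
#'   permutation test (p is then \code{NA}).
#' @param seed Optional integer seed for the permutation draw.
#' @return A \code{maxstat_result}: list with \code{cutoff},
#'   \code{statistic} (signed standardized log-rank statistic at the
#'   cutoff), \code{scanned_cutpoints}, \code{cutpoint_statistics},
#'   \code{p_value}, \code{n_perm}.
#' @export
maxstat_cutoff <- function(scores, surv, minprop = 0.1, n_perm = 1000,
                           seed = NULL) {
  surv <- as_survival_table(surv)
  if (is.null(names(scores))) stop_ginscore("scores must be named by sample id")
  if (!is.numeric(minprop) || minprop <= 0 || minprop >= 0.5) {
    stop_ginscore("minprop must lie in (0, 0.5)")
  }
  common <- intersect(names(scores), surv$sample_id)
  if (length(common) < length(scores) || length(common) < nrow(surv)) {
    message(
      "maxstat_cutoff: ",
      (length(scores) - length(common)) + (nrow(surv) - length(common)),
      " unmatched sample(s) dropped"
    )
  }
  if (length(common) < 3) stop_ginscore("fewer than 3 aligned samples")
  surv <- surv[match(common, surv$sample_id), , drop = FALSE]
  x <- scores[common]
  if (sum(surv$event) < 1) stop_ginscore("no events")
  n <- length(x)
  a <- logrank_scores(surv$time, surv$event)
  ord <- order(x)
  x_s <- x[ord]
  a_s <- a[ord]
  ks <- which(x_s[-n] < x_s[-1]) # split after position k
  min_count <- minprop * n
  ks <- ks[pmin(ks, n - ks) >= min_count]
  if (length(ks) == 0) {
    stop_ginscore("no candidate cutpoint satisfies minprop = ", minprop)
  }
  z <- unname(standardized_split_stats(a_s, ks))
  cutpoints <- unname((x_s[ks] + x_s[ks + 1]) / 2)
  best <- which.max(abs(z)) # first max = lowest cutoff on ties
  obs_max <- abs(z[best])
  p_value <- NA_real_
  if (n_perm > 0) {
    perm_max <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        max(abs(standardized_split_stats(sample(a_s), ks)))
      }, numeric(1))
    })
    p_value <- (1 + sum(perm_max >= obs_max)) / (n_perm + 1)
  }
  structure(
    list(
      cutoff = cutpoints[best],
      statistic = z[best],
      scanned_cutpoints = cutpoints,
      cutpoint_statistics = z,
      p_value = p_value,
      n_perm = n_perm,
      minprop = minprop,
      n = n
    ),
    class = "maxstat_result"
  )
}

#' @export
print.maxstat_result <- function(x, ...) {
  cat(sprintf(
    "maxstat: cutoff = %.4g (|Z| = %.3f over %d candidates, n = %d)\n",
    x$cutoff, abs(x$statistic), length(x$scanned_cutpoints), x$n
  ))
  if (!is.na(x$p_value)) {
    cat(sprintf("permutation p = %.4g (%d permutations)\n", x$p_value, x$n_perm))
  }
  invisible(x)
}

#' Dichotomize scores at a cutoff
#'
#' High group is \code{score > cutoff} (strict), low group otherwise.
#'
#' @param scores Named numeric vector.
#' @param cutoff Numeric cutoff.
#' @return Factor with levels \code{low}, \code{high}.
#' @export
dichotomize_scores <- function(scores, cutoff) {
  factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
}
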