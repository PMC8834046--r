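# Kaplan-Meier, log-rank, Cox and the maximally selected cutpoint.

test_that("survival tables are validated", {
  expect_error(make_surv(c(-1, 2), c(1, 0)), "negative")
  expect_error(make_surv(c(1, 2), c(1, 2)), "0 or 1")
  expect_error(as_survival_table(data.frame(time = 1, event = 1)), "sample_id")
  expect_error(make_surv(c(1, 2), c(1, 0), ids = c("a", "a")), "duplicated")
})

test_that("km_estimate reproduces the product-limit arithmetic", {
  all_cens <- km_estimate(make_surv(c(5, 8, 12), c(0, 0, 0)))
  expect_true(all(all_cens$survival_probs == 1))

  km <- km_estimate(make_surv(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(km$event_times, c(1, 2, 3))
  expect_equal(km$survival_probs, c(2 / 3, 1 / 3, 0))
  expect_equal(km$at_risk, c(3, 2, 1))

  km10 <- km_estimate(make_surv(c(10, 20, 30), c(1, 1, 1)))
  expect_equal(km10$event_times, c(10, 20, 30))
  expect_equal(km10$survival_probs, km$survival_probs)

  # monotone, within [0, 1], for arbitrary censoring patterns
  set.seed(3)
  for (i in 1:10) {
    s <- make_surv(rexp(20, 0.1), rbinom(20, 1, 0.6))
    kk <- km_estimate(s)
    expect_true(all(diff(kk$survival_probs) <= 1e-12))
    expect_true(all(kk$survival_probs >= 0 & kk$survival_probs <= 1))
  }
})

test_that("logrank_test matches the hand-built risk-set computation", {
  # 6-patient instance worked through the O-E / V table
  tA <- c(1, 3, 5)
  eA <- c(1, 1, 0)
  tB <- c(2, 4, 6)
  eB <- c(1, 1, 1)
  ht <- logrank_test(make_surv(tA, eA), make_surv(tB, eB))
  chi_hand <- logrank_oracle(c(tA, tB), c(eA, eB), rep(c(1, 0), each = 3))
  expect_equal(unname(ht$statistic), chi_hand, tolerance = 1e-10)

  set.seed(53)
  for (i in 1:20) {
    n <- sample(6:25, 1)
    time <- round(rexp(n, 0.1), 3)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    g <- rep_len(c(1, 0), n)
    ht_i <- logrank_test(
      make_surv(time[g == 1], event[g == 1]),
      make_surv(time[g == 0], event[g == 0])
    )
    expect_equal(
      unname(ht_i$statistic),
      logrank_oracle(time, event, g),
      tolerance = 1e-8
    )
    # label swap leaves the test unchanged
    expect_equal(
      logrank_test(
        make_surv(time[g == 0], event[g == 0]),
        make_surv(time[g == 1], event[g == 1])
      )$p.value,
      ht_i$p.value
    )
  }

  ident <- make_surv(c(1, 2, 3), c(1, 0, 1))
  ident2 <- make_surv(c(1, 2, 3), c(1, 0, 1), ids = c("x", "y", "z"))
  ht_same <- logrank_test(ident, ident2)
  expect_equal(unname(ht_same$statistic), 0, tolerance = 1e-12)
  expect_equal(ht_same$p.value, 1)

  expect_error(
    logrank_test(make_surv(1:3, c(0, 0, 0)), make_surv(1:3, c(0, 0, 0))),
    "no events"
  )
})

test_that("cox_fit agrees with direct Efron partial-likelihood maximization", {
  set.seed(59)
  n <- 20
  x <- rep(0:1, each = 10)
  time <- round(rexp(n, 0.1 * exp(0.8 * x)), 1) # rounding forces ties
  event <- rbinom(n, 1, 0.8)
  surv <- make_surv(time, event, grp = x)
  fit <- cox_fit(surv, "grp")
  beta_oracle <- stats::optimize(
    efron_nll,
    interval = c(-5, 5), time = time, event = event, x = x,
    tol = 1e-10
  )$minimum
  expect_equal(unname(fit$coefficients), beta_oracle, tolerance = 1e-6)
  expect_equal(unname(fit$hazard_ratios), exp(beta_oracle), tolerance = 1e-5)
  expect_true(fit$ci95[1, "lower"] <= fit$hazard_ratios[1])
  expect_true(fit$ci95[1, "upper"] >= fit$hazard_ratios[1])
})

test_that("cox_fit validates covariates and expands factors", {
  surv <- make_surv(c(1, 2, 3, 4), c(1, 1, 0, 1),
    arm = c("a", "b", "c", "a"), flat = rep(1, 4)
  )
  expect_error(cox_fit(surv, "flat"), "constant")
  expect_error(cox_fit(surv, "nope"), "not found")
  fit <- suppressWarnings(cox_fit(surv, "arm"))
  expect_length(fit$coefficients, 2) # 3 levels -> 2 reference-coded terms
  expect_error(
    cox_fit(make_surv(1:3, c(0, 0, 0), g = c(1, 0, 1)), "g"),
    "no events"
  )
})

test_that("null-covariate Cox intervals cover HR 1 and HR 3.5 fits are unbiased", {
  set.seed(61)
  cover_null <- 0
  reps <- 300
  for (i in 1:reps) {
    te <- rexp(60, 0.02)
    tc <- runif(60, 0, 80)
    surv <- make_surv(pmin(te, tc), as.integer(te <= tc),
      g = rep(0:1, each = 30)
    )
    f <- cox_fit(surv, "g")
    if (f$ci95[1, "lower"] <= 1 && 1 <= f$ci95[1, "upper"]) {
      cover_null <- cover_null + 1
    }
  }
  expect_gte(cover_null / reps, 0.93)

  betas <- numeric(reps)
  for (i in 1:reps) {
    g <- rep(0:1, each = 43)
    te <- rexp(86, 0.004 * 3.5^g)
    tc <- runif(86, 0, 120)
    f <- cox_fit(
      make_surv(pmin(te, tc), as.integer(te <= tc), g = g), "g"
    )
    betas[i] <- f$coefficients[1]
  }
  expect_lt(abs(mean(betas) - log(3.5)), 0.15)
})

test_that("ph_assumption_check is calibrated and detects crossing hazards", {
  surv <- make_surv(c(2, 4, 6, 8, 10, 12), c(1, 1, 0, 1, 1, 0),
    g = rep(0:1, 3)
  )
  tab <- ph_assumption_check(cox_fit(surv, "g"))
  expect_equal(tab$covariate, "g")
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))

  set.seed(67)
  # proportional world: rejections near the nominal level
  rej <- 0
  for (i in 1:200) {
    g <- rep(0:1, each = 50)
    te <- rexp(100, 0.03 * 2^g)
    tc <- runif(100, 0, 60)
    f <- cox_fit(make_surv(pmin(te, tc), as.integer(te <= tc), g = g), "g")
    if (ph_assumption_check(f)$p_value <= 0.05) rej <- rej + 1
  }
  expect_lte(rej / 200, 0.08)

  # effect reversing mid-study: piecewise-exponential sampler, HR e^1 then e^-1
  draw_cross <- function(n, t0 = 5, l0 = 0.08) {
    g <- rep(0:1, each = n / 2)
    r1 <- l0 * exp(1 * g)
    r2 <- l0 * exp(-1 * g)
    t1 <- rexp(n, r1)
    te <- ifelse(t1 < t0, t1, t0 + rexp(n, r2))
    tc <- runif(n, 0, 40)
    make_surv(pmin(te, tc), as.integer(te <= tc), g = g)
  }
  hits <- 0
  for (i in 1:100) {
    f <- cox_fit(draw_cross(200), "g")
    if (ph_assumption_check(f)$p_value <= 0.05) hits <- hits + 1
  }
  expect_gte(hits / 100, 0.5)
})

test_that("maxstat_cutoff splits a perfectly separated cohort between 5 and 6", {
  scores <- setNames(1:10, paste0("s", 1:10))
  # events only among scores > 5, with shorter times
  time <- c(rep(50, 5), 1:5)
  event <- c(rep(0, 5), rep(1, 5))
  ms <- maxstat_cutoff(scores, make_surv(time, event), minprop = 0.2, n_perm = 0)
  expect_gt(ms$cutoff, 5)
  expect_lt(ms$cutoff, 6)
})

test_that("maxstat_cutoff equals the exhaustive-scan oracle", {
  set.seed(71)
  for (i in 1:30) {
    n <- sample(8:50, 1)
    x <- setNames(round(rnorm(n), sample(c(1, 6), 1)), paste0("s", 1:n))
    te <- rexp(n, 0.05 * exp(0.4 * scale(x)[, 1]))
    tc <- runif(n, 0, 40)
    surv <- make_surv(pmin(te, tc), as.integer(te <= tc), ids = names(x))
    if (sum(surv$event) == 0) next
    ms <- try(maxstat_cutoff(x, surv, minprop = 0.1, n_perm = 0), silent = TRUE)
    oracle <- maxstat_oracle(unname(x), surv$time, surv$event, 0.1)
    if (inherits(ms, "try-error")) {
      expect_null(oracle)
    } else {
      expect_equal(ms$cutoff, oracle$cut, tolerance = 1e-12)
      expect_equal(ms$statistic, oracle$z, tolerance = 1e-9)
    }
  }
})

test_that("maxstat_cutoff rejects degenerate inputs", {
  x <- setNames(rep(1, 10), paste0("s", 1:10))
  surv <- make_surv(1:10, rep(1, 10))
  expect_error(maxstat_cutoff(x, surv, n_perm = 0), "no candidate")
  expect_error(
    maxstat_cutoff(setNames(1:10, paste0("s", 1:10)), surv, minprop = 0.6),
    "minprop"
  )
})

test_that("maxstat recovers a planted score threshold", {
  set.seed(7)
  hits <- 0
  reps <- 200
  for (i in 1:reps) {
    x <- setNames(rnorm(86), paste0("s", 1:86))
    hi <- x > stats::median(x)
    te <- rexp(86, 0.006 * 3.5^hi)
    tc <- runif(86, 0, 120)
    surv <- make_surv(pmin(te, tc), as.integer(te <= tc), ids = names(x))
    ms <- maxstat_cutoff(x, surv, minprop = 0.1, n_perm = 0)
    band <- stats::quantile(x, c(0.4, 0.6)) # central 20% around the truth
    if (ms$cutoff >= band[1] && ms$cutoff <= band[2]) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.70)
})

test_that("a score-driven cohort yields the expected high-risk survival pattern", {
  set.seed(83)
  ok <- 0
  reps <- 50
  for (i in 1:reps) {
    cfg <- sim_config(n_samples = 86, seed = 1000 + i)
    sc <- setNames(stats::rnorm(86), sprintf("S%03d", 1:86))
    surv <- simulate_survival(sc, cfg)
    ms <- maxstat_cutoff(sc, surv, n_perm = 0)
    grp <- dichotomize_scores(sc[surv$sample_id], ms$cutoff)
    lr <- logrank_test(surv[grp == "high", ], surv[grp == "low", ])
    surv$gin_group <- grp
    # monotone-likelihood warnings (quasi-complete separation) are expected
    # in a few replicates with this effect size
    cx <- suppressWarnings(cox_fit(surv, c("gin_group", "arm", "histology")))
    if (lr$p.value < 0.05 && cx$hazard_ratios["gin_grouphigh"] > 1) ok <- ok + 1
  }
  expect_gte(ok / reps, 0.90)
})

test_that("dichotomization is strict at the cutoff", {
  g <- dichotomize_scores(c(a = 1, b = 2, c = 3), 2)
  expect_equal(as.character(g), c("low", "low", "high"))
})
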