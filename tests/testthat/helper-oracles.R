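# Independent brute-force oracles and small fixture generators. These
# deliberately use naive loop-based formulations so they share no code
# path with the package implementations they check.

# Random valid segment profile: disjoint intervals per chromosome.
rnd_profile <- function(id = "s1", n_seg = sample(10:50, 1)) {
  chroms <- sample(as.character(1:22), n_seg, replace = TRUE)
  segs <- do.call(rbind, lapply(split(seq_along(chroms), chroms), function(idx) {
    k <- length(idx)
    bounds <- sort(sample.int(1e6, 2 * k))
    data.frame(
      chrom = chroms[idx[1]],
      start = bounds[seq(1, 2 * k, 2)],
      end = bounds[seq(2, 2 * k, 2)],
      log2_ratio = runif(k, -1, 1),
      stringsAsFactors = FALSE
    )
  }))
  segment_profile(id, segs)
}

# FGA by explicit per-segment summation.
brute_fga <- function(profile, thr = 0.2) {
  seg <- profile$segments
  tot <- 0
  alt <- 0
  for (i in seq_len(nrow(seg))) {
    len <- seg$end[i] - seg$start[i]
    tot <- tot + len
    if (abs(seg$log2_ratio[i]) > thr) alt <- alt + len
  }
  alt / tot
}

# Single-sample enrichment score by an explicit position-by-position
# ECDF walk.
es_oracle <- function(values, set_genes, alpha) {
  r <- rank(values, ties.method = "average")
  ord <- names(r)[order(-r, names(r), method = "radix")]
  n <- length(r)
  inset <- ord %in% set_genes
  m <- sum(inset)
  denom <- sum(r[ord][inset]^alpha)
  es <- 0
  cin <- 0
  cout <- 0
  for (i in seq_len(n)) {
    if (inset[i]) {
      cin <- cin + r[[ord[i]]]^alpha / denom
    } else {
      cout <- cout + 1 / (n - m)
    }
    es <- es + (cin - cout)
  }
  es
}

# Log-rank chi-square by explicit risk-set tables (hypergeometric
# moments at each distinct event time).
logrank_oracle <- function(time, event, group) {
  O <- 0
  E <- 0
  V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Negative Efron partial log-likelihood for a single covariate.
efron_nll <- function(beta, time, event, x) {
  eta <- x * beta
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sw <- sum(w[R])
    swd <- sum(w[D])
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1) ll <- ll - log(sw - l / d * swd)
  }
  -ll
}

# Maximally selected standardized log-rank statistic by naive full scan:
# Nelson-Aalen scores recomputed per sample with double loops, every
# admissible cutpoint evaluated directly.
maxstat_oracle <- function(x, time, event, minprop) {
  n <- length(x)
  a <- numeric(n)
  for (i in seq_len(n)) {
    L <- 0
    for (t in sort(unique(time[event == 1]))) {
      if (t <= time[i]) L <- L + sum(time == t & event == 1) / sum(time >= t)
    }
    a[i] <- event[i] - L
  }
  xs <- sort(unique(x))
  best <- NULL
  for (j in seq_len(length(xs) - 1)) {
    cut <- (xs[j] + xs[j + 1]) / 2
    high <- x > cut
    m <- sum(high)
    if (m < minprop * n || (n - m) < minprop * n) next
    abar <- mean(a)
    S <- sum(a[high])
    V <- m * (n - m) / (n * (n - 1)) * sum((a - abar)^2)
    z <- (S - m * abar) / sqrt(V)
    if (is.null(best) || abs(z) > abs(best$z)) best <- list(cut = cut, z = z)
  }
  best
}

# Survival table from bare vectors.
make_surv <- function(time, event, ids = paste0("s", seq_along(time)), ...) {
  as_survival_table(data.frame(
    sample_id = ids, time = time, event = event, ...,
    stringsAsFactors = FALSE
  ))
}

# Random correlation table over a shared gene universe.
rnd_cor_table <- function(genes, cohort) {
  correlation_table(genes, runif(length(genes), -1, 1), cohort, 50)
}
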