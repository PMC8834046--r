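---
title: "Methods: a gene-expression surrogate of genomic instability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a gene-expression surrogate of genomic instability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ginscore)
```

## The problem

Oral potentially malignant disorders (OPMD, e.g. oral leukoplakia) transform
into oral squamous cell carcinoma at rates that vary enormously between
patients, and genomic instability — the accumulation of copy-number gains
and losses — is one of the few processes consistently tied to that risk.
Measuring instability directly requires copy-number profiling, which many
expression-only cohorts lack. `ginscore` implements the alternative: a
transcriptomic *surrogate* of genomic instability, derived once from
cohorts where both expression and copy-number are available, then applied
to any expression matrix.

The pipeline has four stages, each an exported module:

1. **FGA** — quantify instability per sample as the fraction of genome
   altered, from segmented copy-number profiles.
2. **Signature derivation** — correlate every gene's expression with FGA
   in two independent cohorts and keep the genes that pass a correlation
   threshold in both.
3. **Scoring** — summarize the signature in each sample with a
   single-sample enrichment statistic (the GIN score).
4. **Association** — relate the score to phenotype groups and to
   time-to-cancer outcomes, including a maximally selected cutpoint that
   dichotomizes the score into high/low instability groups.

## Fraction of genome altered

For a profile of segments with lengths $\ell_i$ and copy-number log-ratios
$v_i$,

$$\mathrm{FGA} \;=\; \frac{\sum_{i\,:\,|v_i| > t}\,\ell_i}{\sum_i \ell_i},
\qquad t = 0.2 .$$

The magnitude is thresholded, so deletions count as alteration on equal
footing with amplifications; the inequality is strict. A `linear = TRUE`
flag applies the same threshold to $|v_i - 1|$ for pipelines that emit
linear rather than log2 ratios. Sex chromosomes receive no special
handling and there is no ploidy correction — the fraction is a pure length
ratio over whatever segments were measured.

Coordinates are handled in 0-based half-open form internally (length is
`end - start`); SEG files on disk are treated as 1-based inclusive and
converted on read. Rows with a non-finite segment mean are dropped with a
reported count — imputing a copy-number state for an unmeasured segment
would silently bias the denominator, whereas dropping only narrows it.

Useful invariants, all property-tested: FGA lies in $[0,1]$; it is
non-increasing in the threshold; it is invariant to rescaling all
coordinates and to splitting a segment into abutting pieces with the same
ratio.

## Signature derivation

Within each cohort, every gene with non-zero expression variance gets a
Pearson correlation $r$ between its expression vector and the per-sample
FGA. Samples are matched by identifier, and mismatches are reported rather
than silently aligned. The signature at threshold $t$ is

$$S(t) \;=\; \{\,g : r_A(g) \ge t \ \wedge\ r_B(g) \ge t\,\},$$

the plain intersection of the two one-sided filters. Only positive
correlations are eligible by default: the published 20-gene signature this
package ships (see `gin_signature()`) has positive correlations in both
training cohorts, and a gene anti-correlated in one cohort but correlated
in the other is evidence of inconsistency, not signal. An `absolute` flag
exposes the magnitude-based alternative for sensitivity analyses.

The default threshold grid $\{0.2, 0.3, 0.35, 0.4\}$ is swept and recorded
in every selection object as an audit trail; 0.35 is the default cutoff
because it lands the signature inside the intended 10–50 gene window on
the published training pair. A size outside that window warns but does not
error — the window is a design target, not a validity condition. No
multiple-testing correction is applied: selection is by effect size
replicated across two cohorts, which is the filter doing the statistical
work.

## The GIN score

Scoring is the classic single-sample GSEA statistic. Per sample, genes are
rank-normalized (ascending ranks, ties averaged). Walking the $N$ genes
from highest to lowest rank — ties in the walk order broken by gene
identifier so results are deterministic — two cumulative curves are
accumulated: the in-set curve advances by $r_g^{\alpha} / \sum_{g' \in S}
r_{g'}^{\alpha}$ at each signature gene, the out-of-set curve by
$1/(N - m)$ at each remaining gene. The score is the *sum* of the
difference over all $N$ positions — the integrated ECDF difference — not
the maximum deviation used by two-group GSEA.

Parameters that matter:

- `alpha` (default 0.25): the rank-weighting exponent. 0 gives the
  unweighted ECDF difference; larger values concentrate weight on the most
  highly expressed signature genes. 0.25 is the conventional default for
  this statistic and is what the package's tests calibrate against.
- `normalize` (default off): divides all scores by their range across the
  scored cohort. It reproduces a common reporting dialect but makes a
  sample's score depend on which other samples were scored with it, so the
  raw statistic is the default contract. Published absolute score values
  (such as a cutoff of 82.88 on one OPMD cohort) live on a scale set by
  the scoring software's version and settings and are not comparable
  across implementations; every downstream step here is scale-adaptive,
  so nothing in this package depends on reproducing any absolute scale.
- Gene matching is exact, case-sensitive symbol equality. Signature genes
  absent from the matrix are ignored if at least half the set is present
  (reported); below that floor, scoring errors out rather than quietly
  scoring a remnant of the signature.

Because only within-sample ranks enter, the score is invariant under any
strictly increasing per-sample transform of the expression values —
log-scale or linear, quantile-normalized or not — and each sample's
(unnormalized) score is independent of the rest of the cohort. Both
properties are asserted in the test suite, and the implementation is
checked exhaustively against an independently coded walk oracle on every
gene universe of size ≤ 8.

## Comparison statistics

Group comparisons use the standard two-sided nonparametric battery:
Mann–Whitney (two groups), Kruskal–Wallis (more than two), Wilcoxon
signed-rank (paired two — the standard reading of a "paired Mann–Whitney"),
and Friedman (paired, more than two). Pearson correlation carries a
p-value from the $t$ transform on $n-2$ degrees of freedom.

Exact versus asymptotic: the Mann–Whitney p is exact for combined
$n \le 12$ without ties; the signed-rank p is exact for $n \le 15$
non-zero differences by enumerating all $2^n$ sign patterns conditional on
the observed magnitudes, which stays exact under tied magnitudes. Beyond
those sizes, normal approximations with tie and continuity corrections are
used. The switchover points keep enumeration effectively instant and are
arguments, not constants. Zero paired differences are dropped before
ranking (Wilcoxon's original rule), with a reported count. The degenerate
all-values-equal Kruskal–Wallis case returns statistic 0, p = 1 by
documented convention.

All five tests are calibration-tested: under their nulls the rejection
rate at $\alpha = 0.05$ must land in $[0.03, 0.07]$ over 2000 seeded
replicates each.

## Survival machinery

Kaplan–Meier estimation, the two-group log-rank test, and Cox
proportional-hazards models follow the standard formulations (Efron
handling of tied event times; Wald confidence intervals and p-values,
matching the usual HR + 95% CI reporting). Proportionality is checked per
covariate via the association of scaled Schoenfeld residuals with
Kaplan–Meier-transformed time.

The maximally selected cutpoint works on log-rank scores
$a_i = \delta_i - \hat\Lambda(t_i)$ (event indicator minus Nelson–Aalen
cumulative hazard). For a candidate cutoff $c$ — midpoints between
consecutive distinct score values whose induced groups both hold at least
`minprop` (default 0.1) of the samples — the statistic is the linear rank
sum $\sum_{x_i > c} a_i$ standardized by its exact permutation mean and
variance. The cutoff is the argmax of the absolute standardized statistic,
ties resolved to the lower cutoff, and samples strictly above the cutoff
form the high-instability group. Because the argmax optimizes over many
candidate splits, the naive log-rank p at the chosen cutoff would be
anti-conservative; inference instead uses a seeded permutation null of the
*maximal* statistic, which accounts for the selection exactly and needs no
distributional approximation. The permutation p is verified to be
uniform-calibrated under the null, and the scan itself is verified against
an exhaustive brute-force oracle on every tested instance up to 50
samples.

## The synthetic-cohort generator

Every stage is testable without external data because the generator
produces cohorts with exactly the structure the analysis assumes — and its
defaults are the study conditions the package is designed around, chosen
once:

- **Copy number**: per sample, a target FGA is drawn from Beta(2, 3)
  (mean 0.4, SD 0.2 — instability on the scale seen in head-and-neck
  carcinoma). A 22-chromosome toy genome with human-autosome length
  proportions (3 Gb total) is cut into 50–200 segments at uniform
  breakpoints; segments are marked altered (ratio magnitude in
  [0.25, 1.5], random sign) greedily in decreasing length order until the
  altered length reaches the target, so the achieved FGA matches the
  target to within one segment (in practice ≤ 0.02); remaining segments
  get ratios in (−0.15, 0.15). The *achieved* fraction is recorded as
  truth, making `compute_fga()` an exact round-trip.
- **Expression**: planted genes follow $5 + \mathrm{FGA} + \varepsilon$
  with $\varepsilon$ Gaussian and SD set so the population correlation
  with FGA equals `target_r` (default 0.5, the middle of the per-gene
  correlations in the published signature); background genes are
  independent Gaussian noise. This is deliberately the *simplest*
  structure detectable by Pearson correlation: no co-expression, no
  batch structure, no heavy tails.
- **Survival**: the planted-set GIN score, standardized, scales an
  exponential hazard with baseline 0.006 events/month and a default log
  hazard ratio of log(3.5) per score SD — the effect size reported for
  the high-instability group in the OPMD chemoprevention-trial setting
  this emulates. Censoring is independent uniform on (0, 120) months
  (a ~10-year trial horizon), yielding roughly 30% events at the null.
  Independent 3-level treatment-arm and 2-level histology covariates are
  attached.
- Everything is driven by one integer seed (R's default Mersenne–Twister
  stream, seeded per sub-generator at fixed offsets), so cohorts are fully
  reproducible and sub-generators can be called independently with
  identical results.

What passing tests on these cohorts shows: the selection rule recovers
planted FGA-coupled genes at the stated sensitivity, the score tracks true
FGA, and the survival machinery recovers planted cutpoints and hazard
ratios — i.e. the machinery is correct and calibrated. What it does not
show: robustness to correlated gene backgrounds, platform noise,
normalization artifacts, or cohort heterogeneity in real tumors; the
generator makes no attempt at those.

## Problem sizes and numerical choices

The test suite exercises: signature recovery on a 200 + 30 sample cohort
pair with 1000 genes and 25 planted at true r = 0.5 (sensitivity ≥ 0.8,
false-discovery proportion ≤ 0.1 at threshold 0.35); score validity on a
held-out 200-sample cohort (r ≥ 0.5 against true FGA); maxstat calibration
over 500 null replicates of 30 samples with 99 permutations each; Cox
interval coverage at true HR 3.5 with 86 samples and ~30% events over 300
replicates; and type-I calibration of the five comparison tests over 2000
replicates each. These sizes are the package's chosen verification scale:
large enough for the binomial error of an empirical rate to sit well
inside the asserted bands, small enough that the whole suite runs in about
a minute.

Numerical tie-breaks worth knowing: expression ties rank-average; the
enrichment walk orders ties by gene identifier; maxstat statistic ties go
to the lower cutoff; duplicate expression rows keep the highest-mean row;
the high survival group is strictly above the cutoff. The enrichment
implementation agrees with its oracle to 1e−12, and FGA round-trips the
generator to 1e−12.

## Known limitations

- The derivation assumes the two training cohorts share gene identifiers;
  no identifier translation is attempted.
- Correlation-based selection sees only linear, consistently signed
  expression–FGA relationships, by design.
- Absolute GIN scores are not comparable across gene-universe sizes or
  `alpha` values, and not to scores from other software; only
  within-cohort contrasts and scale-adaptive downstream steps are
  supported.
- The Cox machinery covers right-censored data with baseline covariates —
  no competing risks, no time-varying covariates.
- The permutation p for the selected cutpoint assumes exchangeability of
  samples under the null (no strata).
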