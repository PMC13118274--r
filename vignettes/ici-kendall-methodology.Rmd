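---
title: "Information-content-informed Kendall-tau: model, choices, limits"
author: "kendallICI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-content-informed Kendall-tau: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kendallICI)
```

## The problem

Analytical instruments have a limit of detection. In metabolomics and
proteomics abundance matrices, a large share of missing cells are
therefore *left-censored*: the analyte was present but too low to
measure. A missing value of this kind is not an absence of information —
it says "below everything observed in this sample". Correlation measures
that drop incomplete pairs (pairwise-complete) throw that information
away; imputing zeros or half-minima fabricates numeric values whose
influence depends on the imputation constant and on how comparable the
detection ranges of the samples are.

## The model

The Kendall correlation is built from concordant and discordant point
pairs, which makes it uniquely easy to extend: we only need to say how a
comparison involving a missing value is ordered. `kendallICI` adopts the
left-censorship reading — a missing value compares below every observed
value, and two missing values compare as tied. Writing the pair census of
two vectors as concordant (`n_con`), discordant (`n_dis`), tied-in-x
(`n_xtie`), tied-in-y (`n_ytie`), tied-in-both (`n_tie`) counts out of
`n_tot = n(n-1)/2` pairs, the correlation is the usual tau-b:

$$\tau_b = \frac{n_{con} - n_{dis}}
  {\sqrt{(n_{tot} - n_{xtie})(n_{tot} - n_{ytie})}}$$

Eight concordance and eight discordance rules cover the
missing-value cases; `countPairsBruteforce()` implements them literally
as the reference. The equivalent fast path (`iciKt()`) replaces missing
entries with a sentinel strictly below the joint observed minimum
(`min - 1 - |min| * 1e-6`, safe for negative data) and computes tau-b in
O(n log n) by sorting plus mergesort exchange counting. Equivalence of
the two paths, to 1e-12 over thousands of randomised pairs with ties and
up to 60% missingness, is asserted in the test suite. When all observed
values are positive, the sentinel path coincides exactly with classical
tau-b after zero-substitution — which is why the method can be described
as "simple imputation plus tau-b" without giving up the information-based
interpretation.

Two *perspectives* handle points missing in both vectors. `local` removes
them (appropriate when only two samples are being compared), `global`
keeps them as pairs tied in both margins, so every pair of samples over
the same feature set sees the same `n_tot`. `iciKt()` defaults to local,
`iciKtMatrix()` to global, matching those use cases.

Three companions are computed from the same census:

* **tau-max** — the largest tau-b attainable given the tie structure,
  $(n_{tot} - n_{xtie} - n_{ytie} + n_{tie}) / \sqrt{(n_{tot} -
  n_{xtie})(n_{tot} - n_{ytie})}$. Dividing a dataset's tau matrix by the
  maximum off-diagonal tau-max (`scaleMax = TRUE`) rescales all pairs by
  one common factor. The option defaults to FALSE: the factor is
  dataset-specific, so scaled values are not comparable across datasets.
  tau-max is computed identically for negatively correlated pairs, where
  its interpretation as an attainable maximum is weaker; it is reported,
  not applied.
* **completeness** — the fraction of positions missing in neither vector,
  always computed on the full vector length (also under the local
  perspective, so it reports the data loss the local removal hid).
* **Mann–Kendall p-value** — normal approximation for
  `S = n_con - n_dis` with the tie-corrected variance (including both
  higher-order tie-product terms), two-sided by default, no continuity
  correction.

Degenerate pairs — everything tied after sentinel substitution, or fewer
than two points left under local removal — yield `NA` with a warning,
never a silent 0: an undefined correlation is not an absent one, and
downstream medians skip `NA` cells.

## The supporting procedures

**Left-censorship test** (`leftCensorshipTest()`). Within each sample
group, every feature that is missing in at least one sample contributes
its *present* values; each counts a success when at or below its own
sample's median of present values (ties at the median count as successes,
reading "less than or equal" literally). Success and failure counts are
aggregated across groups and tested against 0.5 with an exact binomial
test. The test is one-sided toward success by default — left-censorship
is the alternative of interest — and switchable. For batches of datasets,
`leftCensorshipTestBatch()` applies Benjamini–Hochberg across datasets.
One caveat the test inherits from its cell-level design: when samples
share a persistent abundance profile (the realistic case), the
success/failure indicators cluster by feature, the effective sample size
is nearer the number of partially-missing features than the number of
cells, and the test is anticonservative under feature-clustered random
missingness on strongly correlated simulated cohorts (the test suite
bounds, but does not eliminate, this inflation). Its nominal calibration
holds for
exchangeable samples, which is how the suite checks it; with the strong
left-censorship signal the test is meant to detect, p-values are many
orders of magnitude below any reasonable threshold and the inflation is
immaterial.

**Rank diagnostics** (`rankMissingSummary()`). Features are ranked per
sample over present features (rank 1 = lowest). Under left-censorship,
the more samples a feature is missing from, the lower its median rank
where present — a monotone decreasing trend whose Kendall correlation
(`rankMissingCorrelation()`) is strongly negative for censored data and
near zero for random missingness.

**Outlier detection** (`detectOutliers()`). Each sample's median
correlation to its within-group partners is transformed to
`log(1 - cor_median)` and compared, per group, to the upper Tukey fence
`Q3 + 1.5 IQR` (type-7 quantiles — fence positions depend on the
convention, so it is pinned). Only the high end is flagged; an unusually
*good* sample is not an outlier. Median correlations of 1 are clamped to
`1 - 1e-15` before the log; clamping can only lower a score, so it cannot
fabricate an outlier. The natural log is used; the base only shifts
scores additively under the monotone transform, so the flags are
base-invariant. The fence is computed within each group, and the
restriction to the high end is likewise applied per group — the most
conservative reading of the two. The downstream evaluation harness,
`significantFraction()`, runs a per-feature one-way equal-variance F-test
across groups with Benjamini–Hochberg adjustment; moderated-variance
(empirical-Bayes) statistics are deliberately out of scope, so fractions
are comparable within this package but not to moderated-test pipelines.

**Networks** (`partialCorrelations()`, `selectEdges()`,
`partitionRatio()`). Feature–feature correlations are converted to
partial correlations via the standardised negative inverse correlation
matrix. With far more features than samples the sample correlation matrix
is singular; since no particular estimator is canonical here, the package
shrinks toward the identity with the smallest intensity that lifts the
minimum eigenvalue to 0.01 (an explicit, reproducible rule recorded in
the `"shrinkage"` attribute). Edges are the off-diagonal entries beyond
the 2.5% and 97.5% empirical quantiles (inclusive at the thresholds, so
quantile ties resolve deterministically), trimmed to positive weights.
The partitioning ratio

$$Q = \sum_i \left( \frac{within_i}{annotated}
  - \left(\frac{outer_i}{annotated}\right)^2 \right)$$

scores how much edge weight stays inside annotation sets. A crossing edge
i–j counts in `outer` once from each side by default (`crossCounting =
"both"`), the directional "start node" reading; `"once"` is available.
For disjoint single-membership annotations Q is at most 1 (fully
partitioned) and the analytic extremes (1 for all-within, −2 for a
two-set all-crossing graph) are asserted exactly in the tests;
overlapping annotation sets widen the range.

## The simulation suite

The generators are pure functions of their parameters and a mandatory
seed (seeded via `withr::with_seed`, leaving the caller's RNG stream
untouched), and they define the package's validation conditions:

* `simPerfectPair()` — n = 1000 draws from log-normal(meanlog 1, sdlog
  0.5), sorted; partner = values plus uniform(−0.5, 0.5) noise,
  re-sorted, so Kendall starts at exactly +1. The *negative* pair negates
  the re-sorted partner rather than merely reversing it: reversing an
  asymmetric (log-normal) sample gives a Pearson correlation well away
  from −1 and large Pearson shifts under censoring, whereas the negated
  partner is a linear mirror with Pearson essentially at −1 — the
  construction consistent with a pair that is perfectly anti-correlated
  for both rank and linear measures. Values being negative is irrelevant
  to either correlation.
* `simInsertLowMissing()` — censors up to 499 positions sampled from the
  lowest half of one vector's values (the low end of that vector's own
  distribution, whichever way it is ordered).
* `simAddOutliers()` — perturbs 0.5% of points at the high end with
  uniform(−0.5, 0.5) + log-normal(meanlog 1.2, sdlog 0.1) noise.
* `simRealisticPair()` — a log-normal base sample plus one partner with
  additive normal(0, 0.2) noise. With noise on one partner the pair
  starts at an ICI-Kt of about 0.90, the intended starting correlation
  of the realistic benchmark (noising both copies independently starts
  the pair noticeably lower), so the single-noised reading is adopted as
  the generator's definition.
* `censorCutoff()` (grid 0–1.5 by 0.1) and `censorRandom()` (0–300 by
  50) — the left-censoring and missing-at-random mechanisms.
* `simLodCohort()` — a shared log-scale base profile (normal mean 1, sd
  0.5), per-sample normal(0, 0.2) noise on that scale, exponentiated and
  then log10-transformed so values represent orders of magnitude;
  `censorDynamicRange()` censors each sample below its minimum plus a
  uniform(0, level) draw, with levels 0.5 / 1 / 1.5 as low / medium /
  high dynamic-range variability, and `halfMinImpute()` provides the
  conventional global imputation partner.

What the simulations emulate — and what they do not. They capture the
log-like abundance distribution, a persistent feature profile across
samples, LOD-style censoring and random missingness. They do not emulate
multimodal abundance distributions, batch effects, day-to-day drift of
the detection limit, NMR-versus-MS missingness profiles, or correlated
feature blocks beyond the block design used in the network property test.
Passing tests therefore demonstrate the algebraic and statistical
behaviour of the methods under controlled censorship, not performance on
any particular real dataset.

## Numerical and design notes

* All pair counts are exact integers carried in doubles (exact below
  2^53); floating point enters only at the final ratios.
* The matrix engine evaluates pair-index chunks and reassembles by index,
  so results are bit-identical for 1, 2 or 8 workers; parallelism is a
  convenience, never a semantics.
* Completeness compositing multiplies the *unscaled* tau: completeness is
  a per-pair data-quality weight, tau-max scaling a dataset-level
  normalisation, and applying the weight first keeps the composite
  independent of the scaling decision.
* Diagonal entries of correlation sets are computed, not assumed, so a
  sample's self-completeness honestly reports its own missingness.
* Text I/O is TSV-canonical with CSV sniffed on input; missing encodings
  `""`, `"NA"`, `"NaN"` are configurable and exact zeros can be declared
  missing, since public repositories use both conventions.

## Problem sizes used in the checks

The behavioural suite runs the simulations at the sizes the methodology
is defined at — pairs of n = 1000, cohorts of 10 x 1000, 100 replicate
seeds for the correlation-deviation checks, 200 replicates for the
censorship discrimination, 100 for outlier recovery and the network
partitioning property — and the complexity check regresses runtime over
n from 10^3 to 10^5. The oracle-equivalence property uses vectors up to
n = 50, where the O(n^2) reference enumeration is still comfortable.

## Known limitations

Right-censorship (values above an upper detection bound) and mixed
censoring mechanisms are out of scope. The binomial censorship test's
cell-level aggregation is anticonservative for strongly correlated
samples, as discussed above. tau-max scaling is within-dataset only. The
partial-correlation estimator is a pragmatic regularisation, not an
optimised graphical-model estimator; with extreme feature/sample ratios
its shrinkage intensity approaches 1 and edges shrink toward marginal
correlations. The outlier evaluation harness uses the ordinary F-test,
not moderated statistics.
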