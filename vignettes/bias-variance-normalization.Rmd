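---
title: "Normalization as a bias-variance trade-off: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalization as a bias-variance trade-off}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normbench)
```

## The problem

Post-summarization normalization of log2 expression matrices (one value
per gene and array) is meant to remove technical array-to-array
variation before two-group differential expression testing.  Every such
procedure, however, estimates the technical component from the data —
and the estimate unavoidably absorbs some biological signal.  The result
is a trade-off: normalization *reduces the per-gene noise variance*
(raising testing power) while *shifting the expected group differences*
(introducing bias that inflates false positives).  `normbench` makes
both sides of that trade-off measurable: closed-form predictions where
they exist, Monte-Carlo predictions elsewhere, and a simulation harness
that scores complete gene-selection strategies (normalization × test ×
multiple-testing procedure) by true and false positive counts.

## The generating model

The simulators draw from an equicorrelated random-effect model.  With
`G` genes, `n` arrays per group, and groups `A` (phenotype of interest)
and `B` (reference),

$$X_{gjk} = \mu_{gk} + b_{jk} + e_{gjk}, \qquad
  b_{jk} \sim N(0, \rho\sigma^2), \quad
  e_{gjk} \sim N(0, (1-\rho)\sigma^2),$$

where $b_{jk}$ is shared by all genes on array $j$ of group $k$ (the
technical array effect) and $e_{gjk}$ is independent noise.  Every gene
then has total variance $\sigma^2$ and every pair of distinct genes
correlation $\rho$.  Group-B means are zero; group-A means are
$\mu_+ > 0$ for the up-regulated set $\Gamma_+$ (size $N_+$),
$\mu_- < 0$ for $\Gamma_-$ (size $N_-$), zero for the null set.  The
fractions $\gamma_\pm = N_\pm/G$ and the *differential imbalance*
$\bar\delta = \gamma_+\mu_+ + \gamma_-\mu_-$ drive all bias formulas
below.  A structure is *balanced* when $\bar\delta \approx 0$.

### Default parameters and where they come from

| parameter | default | meaning |
|---|---|---|
| `G` | 1000 | genes per simulated dataset (presets) |
| `n` | 10 | arrays per group (SIMU1 preset) |
| `sigma2` | 0.1286 | total per-gene log2 variance |
| `rho` | 0.894 | common intergene correlation |
| DEG split | 50/50 or 60/40 | balanced / unbalanced of 100 DEGs |
| effect sizes | ±1.0, ±1.8 | "small" / "large" log2 fold changes |
| `reps` | 20 | replicates per grid cell |

`sigma2` and `rho` jointly describe a typical large childhood-leukemia
microarray cohort, where the average per-gene log2 variance is near
0.13–0.15 and the mean pairwise intergene correlation is close to 0.9.
They are mutually constrained: under the model, mean-centering each
array leaves residual variance $\sigma^2(1-\rho)(1-1/G)$, and the pair
(0.1286, 0.894) makes the pre- and post-centering variances internally
consistent at roughly 0.1286 and 0.0137.  Both are ordinary config
fields, not constants.

The SIMU1 per-group sample size of 10 represents the "small-sample"
regime these designs probe; SIMU2/3 treat `n` as the tuning parameter
(a grid of 5–80 spans small to large cohorts).  Effect-size grids of
0.2–1.8 bracket the regime where normalization helps and the regime
where its bias dominates.

### The resampling simulator and the synthetic seed matrix

`simulate_resample()` emulates benchmarking against real arrays:
permute the arrays of a seed cohort, split the first `2n` into two
pseudo-groups (exchangeable, hence null), then spike recorded effect
sizes into group A.  Because real cohort data ship outside this
package's scope, `synthetic_seed_matrix()` provides a synthetic stand-in
built to match cohort-level summary statistics: gene-specific variances
drawn around 0.15, a shared array effect giving correlation near 0.9,
baselines near 7 log2 units, and a mild per-array scale distortion of
within-array deviations.  The distortion is deliberately *non-additive*
on the log scale: mean-centering cannot remove it, rank and quantile
normalization absorb it, which reproduces the qualitative ordering of
procedures seen on real cohorts.

What the generators do *not* emulate: heavy-tailed and skewed expression
distributions, intensity-dependent (curved) technical effects,
correlated gene blocks/pathway structure, and probe-level artifacts.
Passing tests therefore demonstrate correctness of the machinery and of
the model-level predictions, not performance guarantees on any
particular real dataset.

## The procedures

* **none** — baseline.
* **global** (`normalize_global`) — subtract each array's mean.  Exact
  bias: the subtracted mean has expectation $\bar\delta$ in group A, so
  expected differences become $\mu_\pm - \bar\delta$ (DEGs) and
  $-\bar\delta$ (null genes); `predict_bias_global()` is exact and is
  the hard oracle for the Monte-Carlo machinery.  Exact variance:
  $\sigma^2(1-\rho)(1-1/G)$ via `predict_var_global()`.
* **rank** (`normalize_rank`) — fractional midranks within array;
  invariant to any monotone per-array distortion; its bias involves
  order-statistic terms with no simple closed form and is estimated by
  `mc_bias("rank", ...)`.
* **quantile** (`normalize_quantile`) — map every array onto the
  average-order-statistic reference computed from all arrays of both
  groups.  Because the reference pools `n` shifted and `n` unshifted
  arrays, a DEG's effect is roughly halved and every gene absorbs about
  $-\bar\delta/2$; `predict_bias_quantile()` returns exactly this
  *flagged approximation* (it omits rank-skewing corrections), the full
  value coming from `mc_bias("quantile", ...)`.
* **delta** (`delta_pair` + `delta_select`) — sort genes by sample
  variance, difference consecutive pairs (offset 0 and offset 1, the
  last gene wrapping to the first), test the pair differences, and
  report genes whose *both* pairs are rejected.  Differencing cancels
  the shared array effect exactly and leaves pair-difference variance
  $2\sigma^2(1-\rho)$.
* **sva** (`estimate_surrogates` + `sva_test`) — estimate `K`
  orthonormal array-level factors from the SVD of group-mean residuals
  and test the group effect by a nested-model OLS F-test.  No closed
  form is attempted for its bias or variance; it is assessed through the
  evaluation grid only.

### Why delta sorts by within-group variance

The pairing is supposed to match each gene with a *noise* twin.  Sorting
by the total (groups-pooled) sample variance breaks down exactly when it
matters most: a DEG's total variance is inflated by $\mu^2/4$, so at
large effect sizes all DEGs sort into one contiguous block, pair with
each other, and their differences cancel the signal being tested (power
collapses to near zero).  `delta_pair()` therefore defaults to the
within-group (group-centered) pooled variance — the same quantity the
t-test denominator uses — which keeps DEGs interspersed among null
genes.  This choice restores the method's documented behaviour: power
approaching $1-\gamma$ (a DEG in *both* of its pairs with another DEG is
rare) and a stable false-positive count driven by the rare event of a
null gene being paired with a DEG twice.  `sort_by = "pooled"` is
retained for comparison.

### Other numerical choices

* **Quantile/rank ties.**  Rank normalization uses midranks (keeps the
  downstream Wilcoxon consistent); quantile normalization assigns
  reference entries through a stable sort, so ties resolve by original
  gene index, deterministically, and the map is idempotent on tie-free
  data.
* **Odd gene counts in delta.**  The lowest-variance gene is dropped
  with a warning; an even count is assumed by the pairing.
* **Pooled t, not Welch.**  The model has a common per-gene variance in
  both groups; the pooled form is the matching likelihood-based choice.
* **Moderated t.**  The empirical-Bayes prior (`s0^2`, `d0`) is fitted
  by moment matching of log variances; `trigamma` inversion is done by
  root-finding on the log scale.  When the observed log variances have
  literally zero spread the prior variance is taken to be the common
  value itself (no sampling scatter to correct), so the statistic
  reduces exactly to the ordinary t computed with that variance.
* **Wilcoxon.**  Exact enumeration when the total sample size is at
  most 12 with no ties, else the normal approximation with tie and
  continuity corrections.
* **Permutation p-values** use the add-one convention
  $p = (1 + \#\{N^{perm} \ge N^{obs}\})/(1 + B)$; the smallest
  attainable p is $1/(B+1)$ and Bonferroni-adjusted values stay finite.
  A relative tolerance of $10^{-9}$ decides ties between permuted and
  observed statistics so that summation-order rounding cannot flip a
  mathematically tied permutation.
* **Strict rejection.**  A gene is rejected when `p_adj < alpha`
  (strictly).  For continuous p-values this is measure-zero different
  from `<=`; for permutation p-values it is not, and the strict rule is
  applied consistently everywhere.
* **ROC curves** are built on raw p-values: both MTPs are monotone, so
  the induced gene ranking — all an ROC compares — is identical.
* **Seeds.**  Every generator is a pure function of its config
  including the seed; grids derive per-replicate seeds from a master
  seed via a seed table, so cells are reproducible and independent of
  how many replicates other cells use.

## What the test suite runs

The package's checks run at desk scale, chosen so the whole suite
completes in a few minutes on one core: 20 replicates of the
`G = 1000`, `n = 10` preset configurations for the headline variance
and bias quantities; 1000-gene single datasets for size control of each
test (the N-test at a reduced 199–999 permutations); and reduced
replicate counts (6–10) for grid-level comparisons, always judged
against their own replication noise rather than fixed constants.  The
exact-oracle checks (closed-form bias, step-up equivalence, enumeration
oracles) are scale-free.

## Known limitations

* The quantile and rank bias predictors are approximations by design;
  exact order-statistic corrections are out of scope and handled by
  Monte Carlo.
* SVA's number of surrogate variables `K` is a user parameter (default
  2); no permutation-based dimension selection is performed.
* The N-test is applied per gene (univariate); multivariate
  gene-combination testing is out of scope.
* Balanced/unbalanced comparisons at small `n` sit in the deep tails of
  the rejection region, where the bias-driven false-positive inflation
  is a large-`n` phenomenon; the package's comparisons therefore test
  that regime explicitly at larger `n`.
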