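# normbench

Quantifying the bias-variance trade-off of post-summarization
normalization procedures in two-group differential expression analysis.

## What problem this addresses

Before testing genes for differential expression between two phenotypic
groups, log2 expression matrices are usually normalized to remove
technical array-to-array variation.  Every normalization estimates the
technical component *from the data*, and that estimate absorbs some
biological signal: the procedure **reduces per-gene noise variance**
(more power) while **biasing the expected group differences** (more
false positives).  Which side wins depends on the sample size, the
effect sizes, and whether up- and down-regulation are balanced.

`normbench` is for methodologists and analysts who want to measure both
sides of this trade-off.  It implements, as one tested pipeline:

* five normalization procedures — global mean-centering, fractional-rank
  replacement, quantile normalization, the delta-sequence
  (variance-matched gene pairing) method, surrogate variable analysis —
  plus the un-normalized baseline;
* four per-gene tests — pooled two-sample *t*, empirical-Bayes moderated
  *t*, Wilcoxon rank-sum, and an N-statistic (energy-distance)
  permutation test;
* Bonferroni and Benjamini-Hochberg adjustment with strict rejection at
  `p_adj < alpha`;
* closed-form bias/variance predictors where they exist, Monte-Carlo
  predictors elsewhere;
* simulators: an equicorrelated random-effect model and a resampling
  simulator seeded by a synthetic cohort-like matrix;
* an evaluation harness scoring strategies by true/false positives and
  ROC curves.

## The model in brief

Data are generated (and theory derived) under the random-effect model
$X_{gjk} = \mu_{gk} + b_{jk} + e_{gjk}$ with a per-array effect
$b_{jk} \sim N(0,\rho\sigma^2)$ shared by all genes and independent
noise $e_{gjk} \sim N(0,(1-\rho)\sigma^2)$, giving every gene variance
$\sigma^2$ and every gene pair correlation $\rho$.  With DEG fractions
$\gamma_\pm$ at effect sizes $\mu_\pm$, the imbalance
$\bar\delta = \gamma_+\mu_+ + \gamma_-\mu_-$ controls the induced bias:
mean-centering shifts every expected group difference by
$-\bar\delta$ exactly and leaves residual variance
$\sigma^2(1-\rho)(1-1/G)$; quantile normalization roughly halves DEG
effects and shifts genes by about $-\bar\delta/2$.  See the vignette
(`vignettes/bias-variance-normalization.Rmd`) for the full account.

## Worked example

```r
library(normbench)

cfg <- simu_preset("SIMU3", "unbalanced", tuning = 10, seed = 42)
sim <- simulate_random_effect(cfg)
sim$truth
#> truth_set: 1000 genes (60 up @ 1.8, 40 down @ -1.8, 900 null)

avg_within_group_variance(sim$matrix)                     # 0.11316
avg_within_group_variance(normalize_global(sim$matrix))   # 0.01376
avg_within_group_variance(normalize_quantile(sim$matrix)) # 0.06241

d <- group_mean_difference(normalize_quantile(sim$matrix))
mean(d[sim$truth$class_of == "up"])    #  0.997  (true effect: 1.8)
mean(d[sim$truth$class_of == "null"])  # -0.0205 (true effect: 0)

predict_bias_global(sim$truth)
#> bias_prediction [global]
#>   delta_bar = 0.036
#>   E[diff]: up = 1.764, down = -1.836, null = -0.036
predict_var_global(0.1286, 0.894, 1000)  # 0.01362

for (nm in c("none", "global", "quantile", "delta")) {
  out <- run_strategy(sim$matrix, sim$truth, strategy(nm, "t", "bonf"))
  cat(sprintf("%-8s tp = %3d  fp = %3d\n", nm, out$tp, out$fp))
}
#> none     tp = 100  fp =   0
#> global   tp = 100  fp =   2
#> quantile tp =  94  fp =   0
#> delta    tp =  90  fp =  10
```

Reading the output: mean-centering cuts the within-group noise variance
roughly tenfold (0.113 to 0.014), matching the closed-form prediction
0.01362.  Quantile normalization reduces variance less (0.062) and
compresses the up-regulated genes' observed effect from 1.8 to about
1.0 while pushing null genes to about -0.02 — its averaging bias.  At
this large effect size the un-normalized strategy already finds all 100
DEGs with no false positives, so normalization can only add bias; the
delta-sequence pipeline shows its characteristic stable false-positive
count from null genes twice paired with a DEG.

Grid experiments over effect sizes or sample sizes, with replicate
means and standard deviations per strategy, go through `run_grid()`;
`roc_curve()` turns any test result into a threshold sweep.  A thin
command-line wrapper over the same functions is in
`inst/scripts/normbench.R` (subcommands `simulate`, `normalize`,
`test`, `adjust`).

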