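# samfc

Robust differential expression for **paired** two-condition expression
profiles, built for the small-replicate regime where a single corrupted
measurement can silently destroy a gene's evidence.

## The problem and the method

In a paired design each subject contributes one sample per condition, and
gene *g* is summarised by its within-subject differences
*d<sub>gk</sub> = x<sub>g1k</sub> − x<sub>g2k</sub>* (per-pair log fold
changes on log-scale input), modelled as N(μ<sub>g</sub>, σ<sub>g</sub>²).
Two classic failure modes afflict gene ranking here: genes with accidentally
tiny variance produce huge *t* statistics with negligible fold changes, and
outlying expressions wreck both the mean and the variance when *n* is small
(3–15 pairs).

`samfc` combines three ideas:

1. **Minimum β-divergence estimation.** Per-gene location/scale are fitted
   by the reweighted fixed point

   μ ← Σ w<sub>k</sub> d<sub>gk</sub> / Σ w<sub>k</sub>,  σ² ← (1+β) Σ w<sub>k</sub>(d<sub>gk</sub>−μ)² / Σ w<sub>k</sub>,  w<sub>k</sub> = exp{−β(d<sub>gk</sub>−μ)²/(2σ²)},

   run from both an MLE and a median/MAD start with the candidate of lower
   empirical β-divergence objective kept (the objective is multimodal under
   contamination). The **β-weights** w<sub>k</sub> ∈ (0, 1] double as outlier
   scores: a gene with any weight at or below an adaptive cutoff
   δ = min(0.2, min w + 0.1·range w) is flagged, and only flagged genes use
   the robust estimates — clean genes keep the efficient classical ones.
2. **A robust SAM statistic.** u<sub>g</sub> = μ̂<sub>g</sub>/(σ̂<sub>g</sub>/√n + s₀),
   with the fudge factor s₀ chosen over the percentiles of the scaled
   standard deviations by minimising the coefficient of variation of the
   statistic's spread across variance windows.
3. **Fold-change / statistic rank fusion.** Genes are ordered by the average
   of their |β-FC| rank and |β-SAM| rank; the top of the list is selected
   while sign-flip permutation p-values stay below 0.1 (BH-adjusted mode
   available).

The package also ships the simulation benchmark the method is evaluated on
(paired Gaussian genomes with a known DE subset and one-sided
`x* = d + 2·max` outlier contamination), paired *t*-test and Wilcoxon
signed-rank baselines, and confusion/ROC machinery, so every operating
characteristic is reproducible from code.

## Worked example

Simulate a 1,000-gene paired genome (3 pairs, 3% DE, 5% of genes hit by one
outlying expression), run the pipeline, and evaluate against the truth:

```r
library(samfc)

cfg <- simulation_config(n_genes = 1000, prop_de = 0.03, n = 3,
                         contamination = "per_gene_fraction",
                         outlier_genes_fraction = 0.05, seed = 101)
sim <- simulate_paired_expression(cfg)
fit <- samfc(sim$data, seed = 101)
fit
#> Hybrid robust SAM-FC fit
#>   genes: 1000   pairs (n): 3   beta = 0.2
#>   delta = 0.1   s0 = 0.1241 (mad_window)
#>   outlying genes: 51 (5.1%)
#>   selected top genes: 78 (p < 0.1)
```

The cutoff δ = 0.1 flags 5.1% of genes as containing an outlier — matching
the 5% contamination rate — and s₀ = 0.124 is the variance-stabilising
fudge factor. `tidy(fit)` returns the per-gene score table ordered by the
hybrid rank:

```r
head(tidy(fit), 5)
#> # A tibble: 5 × 11
#>   gene_id beta_fc beta_sam p_value p_adjusted is_outlying_gene smallest_weight
#>   <chr>     <dbl>    <dbl>   <dbl>      <dbl> <lgl>                      <dbl>
#> 1 g00315     1.21     7.84 0.00287      0.754 FALSE                      0.824
#> 2 g00483    -1.19    -7.84 0.00262      0.754 FALSE                      0.861
#> 3 g00095     1.28     7.02 0.00562      0.754 FALSE                      0.831
#> 4 g00825    -1.30    -6.98 0.00637      0.754 FALSE                      0.832
#> 5 g00945     1.20     7.53 0.00487      0.754 FALSE                      0.830
```

Calling the top 30 genes (the true DE count) recovers 26 of the 30 planted
DE genes despite the contamination, and the full ranking discriminates
strongly:

```r
conf <- top_n_confusion(match(tidy(fit)$gene_id, sim$data$gene_id),
                        sim$is_de, 30)
cbind(conf, compute_metrics(conf)[, c("tpr", "fdr")])
#>   tp fp  tn fn       tpr       fdr
#> 1 26  4 966  4 0.8666667 0.1333333

roc_auc(-tidy(fit)$avg_rank[match(sim$data$gene_id, tidy(fit)$gene_id)],
        sim$is_de)
#> ROC: AUC = 0.9786, pAUC(FPR <= 0.2) = 0.1878
```

`autoplot(fit)` draws the smallest-β-weight diagnostic (flagged genes below
the δ line), `plot_volcano(fit)` the p-value/fold-change picture, and
`run_experiment()` repeats this over many seeded datasets and averages the
metrics per method. A thin command-line wrapper with `simulate`, `run`,
`evaluate` and `experiment` subcommands is installed at
`inst/scripts/samfc-cli.R`.

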