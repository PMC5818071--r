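# coexnet

Temporal weighted gene coexpression network analysis with paired
control-vs-case network comparison.

## What this package is for

Longitudinal case/control transcriptome studies — the motivating
design is a rodent model in which hyperthermia-induced seizures (HS)
at a young age are followed through acute, latent and chronic stages
(postnatal days P12/P30/P60/P120) against unexposed controls (CTRL) —
ask two questions that single-gene statistics cannot answer: which
*groups* of genes act together, and how does their wiring change with
the condition over time. `coexnet` provides the full workflow:

* **Preprocessing** — log2 transform, quantile normalization
  (mean-of-tied-ranks), probe-to-gene collapsing by mean, top-n
  variance filtering (default 5000 genes).
* **Differential expression** — SAM-style moderated statistic
  `d_i = (mean_HS − mean_CTRL) / (s_i + s0)` with Tusher's
  coefficient-of-variation choice of the fudge factor `s0` and
  permutation-estimated FDR (default target 10%).
* **Network construction** — biweight midcorrelation, unsigned
  soft-threshold adjacency `a_ij = |bicor_ij|^β` (β = 10 by default,
  or selected as the smallest power reaching scale-free fit R² ≥ 0.8),
  topological overlap, average-linkage clustering with a static tree
  cut and a 50-gene minimum module size.
* **Module statistics** — eigengenes (first principal component of the
  standardized module), module membership (kME), gene significance
  versus sample traits with p ≤ 0.05 / module p ≤ 0.1 reporting
  cutoffs, top-10 hub genes by intramodular connectivity (kWithin).
* **Paired network comparison** — modules detected in the CTRL network
  are transferred to the HS network; genes are ranked by kWithin in
  each network and `delta_rank = rank_CTRL − rank_HS` identifies genes
  and modules gaining or losing connectivity; permutation module
  preservation reports `Zsummary = (Zdensity + Zconnectivity)/2`
  against a 1000-gene random "gold" baseline (< 2 no preservation,
  2–10 weak/moderate, > 10 strong).
* **Enrichment** — hypergeometric over-representation against
  user-supplied GMT gene-set collections with the p ≤ 0.05 and
  ≥ 3-overlap reporting rule, plus function-group gene-count
  summaries.
* **qPCR validation** — 2^−ΔΔCt quantification normalized to a
  housekeeping gene (default Gapdh) with a two-sample t test.
* **Synthetic data** — a latent-factor block generator that plants
  modules, condition-specific connectivity gain/loss/destruction and
  mean-shift DE genes, so every stage above is validated by recovering
  known truth.

The methods vignette (`vignettes/coexpression-workflow.Rmd`) documents
the models, the parameter choices and the validation design in detail.

## Worked example

Simulate a two-group study in which one planted 200-gene module is
destroyed (reduced to noise) in the HS condition, then run the paired
analysis:

```r
library(coexnet)

cfg <- synthetic_config(module_sizes = c(200, 200), n_background = 400,
                        n_samples_per_group = 8,
                        loading_range = c(0.5, 0.9),
                        perturbations = c(M2 = "destroy"),
                        de_genes = 25, de_effect = 2, seed = 7)
ds <- generate_dataset(cfg)

run <- run_config(beta = 10, top_n = 800, sam_permutations = 200,
                  n_permutations = 100, gold_size = 400, seed = 7)
res <- run_timepoint_analysis(ds$expr, ds$samples, run)

res$de
#> SAM permutation analysis (200 permutations, s0 = 0.405, pi0 = 1)
#> 29 genes called at delta = 0.29 (estimated FDR 3.45%)

res$preservation[, c("module", "size", "Zdensity", "Zconnectivity",
                     "Zsummary", "class")]
#>      module size Zdensity Zconnectivity Zsummary  class
#> 1 turquoise  108   25.818        -1.701   12.059 strong
#> 2      blue   50   -0.365        -2.136   -1.250   none
#> 3      gold  400   -1.343         0.612   -0.366   none

res$rank_change$module_table
#>      module size median_delta n_gain class
#> 1 turquoise  108         13.5     66  gain
#> 2      blue   50        -23.5     17  loss
```

Reading the output: of the 29 SAM calls, all 25 planted DE genes are
recovered (4 false calls, consistent with the 3.45% estimated FDR
being an estimate). The CTRL-derived `turquoise` module is the core of
the intact planted module — `Zsummary = 12.1`, strong preservation —
while `blue`, the module whose genes were replaced by noise in HS,
shows no preservation (`Zsummary = −1.2`) and loses connectivity
(median rank change −23.5); the random gold baseline sits near zero.
Because ranks are zero-sum, the intact module's genes climb as the
destroyed module's genes fall, which is why `turquoise` is classified
as gaining.

Hub genes per module are in `res$hubs`, per-gene rank changes in
`res$rank_change$gene_table`, and `run_joint_analysis()` adds the
all-sample network with module-trait correlations and GS/kWithin
scatter tables.

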