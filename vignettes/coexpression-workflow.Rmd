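---
title: "Temporal coexpression networks: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal coexpression networks: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`coexnet` implements the analysis arc used in two-condition,
multi-timepoint transcriptome studies of the kind exemplified by rodent
hyperthermic-seizure (HS) models: preprocessing of log2 intensity
matrices, SAM-style permutation differential expression, unsigned
weighted coexpression network construction with module detection,
module/gene-trait statistics, paired control-vs-case network comparison
by intramodular-connectivity rank change, permutation module
preservation (Zsummary), gene-set over-representation, and qPCR
delta-delta-Ct quantification. A synthetic-data generator with planted
ground truth backs every stage, so the whole pipeline is validated by
recovery of known structure rather than by eyeballing real data.

# The network model

For genes $i, j$ the similarity is the biweight midcorrelation
$\mathrm{bicor}(x_i, x_j)$, a robust correlation that downweights
observations further than 9 MADs from the median via Tukey biweights;
genes with zero MAD fall back to mean-centering (an effective Pearson
treatment for that gene). The unsigned adjacency is

$$a_{ij} = |\mathrm{bicor}(x_i, x_j)|^{\beta}, \qquad a_{ii} = 0,$$

with the soft threshold $\beta$ chosen as the smallest power in
$1..20$ whose scale-free topology fit index reaches 0.8 (`beta = 10`
is the fixed workflow default; `pick_soft_threshold()` verifies or
replaces it). The fit index is the $R^2$ of the log-log regression of
binned connectivity frequency on mean bin connectivity, set to 0 when
the slope is non-negative. Note a known property of soft thresholding:
at high powers even pure-noise networks produce high fit indices, so a
good fit is a necessary sanity check, never evidence of real structure;
that evidence comes from module recovery and preservation statistics.

Topological overlap is the standard unsigned form

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}},$$

and $1 - \mathrm{TOM}$ is the clustering dissimilarity.

## Module detection

Modules come from average-linkage hierarchical clustering with a
*static* tree cut — a deliberate simplification of the dynamic
tree-cut family that makes the procedure fully specifiable and
testable. Two details matter:

* The cut position is expressed as a fraction of the merge-height span
  between its 5th percentile and its maximum. Anchoring at the 5th
  percentile (a convention shared with the dynamic tree-cut literature)
  keeps the position insensitive to a single unusually tight gene pair.
* The fraction itself is chosen from a fixed grid (`0.1..0.9` coarse,
  `0.92..0.999` fine) as the candidate producing the most clusters of
  at least `min_module_size` (default 50) genes, with ties resolved
  toward the lower cut. The reason is empirical: tight, near-noiseless
  modules coalesce far below the top of the tree and are merged by a
  high cut, while weak modules (|r| of 0.2-0.45 raised to the 10th
  power) only consolidate just below the top. No single fraction serves
  both regimes; the count-maximizing rule finds the right one in each
  and remains deterministic. Preferring the lower cut on ties yields
  tight, pure modules rather than looser ones that absorb peripheral
  genes — conservative membership was judged more useful for hub and
  preservation statistics than maximal coverage.

Clusters below the minimum size become "grey" (unassigned); surviving
modules are named by color in decreasing size order (turquoise, blue,
brown, ...), which is cosmetic — all tests compare partitions, never
color names.

## Eigengenes and trait statistics

The module eigengene is the first left-singular vector of the
standardized (per-gene zero mean, unit variance) module submatrix over
samples — unit *norm*, sign-oriented so the mean correlation with
member genes is positive. Gene significance (GS) and module-trait
correlations use Pearson correlation with t-distribution p-values
(n − 2 df); bicor is reserved for the network step. Reporting cutoffs
follow the workflow defaults: GS p ≤ 0.05 for genes, p ≤ 0.1 for
modules, 10 hubs per module ranked by intramodular connectivity
(kWithin).

# Paired network comparison

Condition comparison is CTRL-anchored: modules are detected in the
reference (CTRL) network and the labels are copied onto the test (HS)
network built on the same genes at the same $\beta$. Two statistics
describe change:

* **Rank change.** All non-grey genes are ranked by kWithin in each
  network (1 = most connected, ties broken by gene id);
  `delta_rank = rank_ref − rank_test`, so positive values mean the gene
  climbs in the test network. Ranks are global across modules, which
  makes gains comparable between modules; modules are summarized by the
  median member delta (robust) plus the count of gaining genes, and
  classified gain/loss by the sign of the median. No magnitude cutoff
  is imposed — the ordered table is the result.
* **Preservation.** For each module, density (mean off-diagonal test
  adjacency among members) and connectivity (correlation between member
  kWithin in reference and test) are compared with their null
  distribution over random same-size gene sets drawn from the whole
  test network; `Zsummary` is the mean of the two permutation Z scores,
  read against the conventional thresholds (< 2 none, 2-10 weak to
  moderate, > 10 strong). A "gold" module of 1000 random genes is
  scored alongside as a negative control and should sit near 0. This
  two-statistic construction is a deliberate reduction of the large
  composite preservation statistic families to their two core
  ingredients, keeping the permutation-Z construction and thresholds.
  Null sets are drawn from *all* genes rather than non-grey genes only:
  when background genes dominate the grey set, a non-grey-only pool
  would make the null nearly identical to the modules under test and
  collapse the Z scale (we measured Zsummary dropping from ~11 to ~1.8
  for a fully preserved module).

# Differential expression

The SAM statistic is $d_i = (\bar x_{HS,i} - \bar x_{CTRL,i}) /
(s_i + s_0)$ with the equal-variance pooled standard error $s_i$. The
fudge factor $s_0$ is selected by Tusher's criterion — the percentile
of $\{s_i\}$ (grid 0, 5, ..., 100) minimizing the coefficient of
variation of the windowed median absolute deviations of $d$, with 10
quantile windows of $s$. Two calibration facts worth knowing:

* On *heteroscedastic* data (per-gene SDs spanning a decade) the
  criterion selects $s_0$ in the lowest percentiles, as intended.
* On a perfectly homoscedastic null it drifts to the top percentile:
  the observed $s_i$ is independent of the mean difference, so genes
  with accidentally small $s_i$ have inflated $|d|$, and only a large
  $s_0$ flattens that dependence. This is a property of the criterion
  itself, not a defect of the implementation, and is harmless — under
  homoscedasticity every $s_0$ yields an equivalent ranking.

FDR estimation uses B label permutations (default 200): expected order
statistics $\bar d_{(i)}$, calling rule $|d_{(i)} - \bar d_{(i)}| >
\delta$, numerator $\hat\pi_0 \cdot \mathrm{median}_b$ of permuted
exceedances beyond the calling cutoffs, and
$\hat\pi_0 = \min(1, 2 \hat p)$ with $\hat p$ the fraction of observed
$d$ inside the interquartile band of the permuted $d$. The FDR curve is
monotonized to be non-increasing in $\delta$ (each grid point takes the
maximum estimate at that or any larger $\delta$) before the smallest
$\delta$ with estimated FDR at or below the 10% target is selected.
Because the numerator is a median, the estimator can report 0 when
fewer than half the permutations produce any exceedance; under a global
null this occasionally calls one or two genes — the historical behavior
of this estimator class, documented rather than patched.

# The synthetic-data generator

`generate_dataset()` simulates the statistical structure the analysis
assumes — not microarray physics. Module gene $i$ in module $m$:

$$x_{is} = b + l_i u_{ms} + \varepsilon_{is}, \quad
u_{ms} \sim N(0,1), \; l_i \sim U(l_{lo}, l_{hi}), \;
\varepsilon \sim N(0, \sigma^2),$$

with baseline $b = 8$ so values resemble log2 intensities. Defaults
mirror the emulated study design: 2 groups × 4 postnatal time points
(P12/P30/P60/P120) × 8 animals, six modules of 300/250/200/150/100/80
genes plus 1000 background genes, loadings 0.4-0.9, noise SD 1.0.
Connectivity perturbations act on HS samples only, so CTRL is the
shared reference: "gain"/"loss" scale loadings by `gain_factor`
(default 2), "destroy" replaces the module with pure noise.
Differential genes are drawn from the background pool (so DE truth and
perturbation truth never confound each other) and receive a ±`de_effect`
shift of the HS mean. All randomness flows from a single integer seed.

What the generator does *not* emulate — and therefore what passing
tests do not establish about real data: probe-level artifacts, batch
effects, heavy-tailed noise, correlated background, nonstationarity
across time points, or modules with mixed-sign loadings. A latent
factor realization is shared by all members of a module, which has one
subtle consequence: within one simulation the two groups' within-module
correlations differ through their groups' realized factor variances
even without any perturbation. Exchangeability of CTRL and HS under
"none" therefore holds *across* simulations (the mean difference
centers on zero over seeds; measured −0.026 ± 0.11 over 40 seeds), not
conditionally within one — the validation suite tests it accordingly.

# Numerical and interface choices

* Quantile normalization delegates to `limma::normalizeQuantiles(ties =
  TRUE)` (mean-of-tied-ranks dialect), verified against the rank-mean
  definition in the tests; the variance filter (top 5000 by variance,
  ties broken by gene id) runs on the normalized log2 matrix of the
  combined groups per time point.
* The two-group orientation of `d` and of fold changes is fixed by sort
  order of the labels (CTRL < HS), which makes `d` antisymmetric under
  a label swap.
* Adjacency diagonals are stored as 0 so row sums are connectivities;
  TOM diagonals are 1.
* Degenerate inputs degrade loudly but safely: constant genes get zero
  correlation and a flag, zero null SDs give ±Inf (or 0 when observed
  equals the null mean) Z scores with the gold-module caveat, modules
  smaller than 3 genes are skipped in preservation, and a gold size
  exceeding the gene count is capped with a warning.
* The orchestration layer (`run_timepoint_analysis()`,
  `run_joint_analysis()`) is fail-fast: inputs are validated before any
  stage runs, and every stochastic stage takes its seed from the run
  configuration, making report directories byte-reproducible.

# Problem sizes used in validation

The shipped validation suite runs entirely on generated data, sized so
the full suite completes in well under half an hour on a single core:
recovery properties use a 375-gene, three-module layout at the full
64-sample design (at 32 samples recovery is visibly weaker — sample
size follows the study design); preservation calibration uses paired
800-gene datasets with 200-gene modules; the scale-free and
module-size checks use the ~2000-gene default layout. The acceptance
script re-runs the same designs end to end and reports the resulting
fit index, Zsummary pair, minimum module size and estimated FDR.

# Known limitations

* The static cut, even with the automatic height search, cannot
  resolve nested module structure the way iterative dynamic cuts can;
  `cut_height` accepts a numeric fraction for manual control.
* Preservation reduces to two statistics; rank-based composites and
  cross-tissue designs are out of scope.
* Blockwise construction for very large gene sets (> 20k) is not
  implemented; the dense matrices are quadratic in gene count.
* Enrichment requires an explicit universe (default: the union of the
  collection's members). Web-tool analyses that claim "no background"
  are not reproducible exactly — a hypergeometric test always has a
  universe, and ours is logged.
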