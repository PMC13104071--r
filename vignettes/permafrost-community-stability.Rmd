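---
title: "Methods: community assembly, stability and carbon along permafrost profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community assembly, stability and carbon along permafrost profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(permacomm)
```

`permacomm` chains the community-ecology inferences used on depth-resolved
permafrost microbiome profiles: diversity, null-model stochasticity, the
Sloan neutral community model, SparCC co-occurrence networks with
robustness analysis, AVD community stability, core-taxon identification, a
degradation index, and the association between stability and organic
carbon density (POCD). This vignette documents the models, the tunable
parameters, the numerical conventions, and what the synthetic generator
does and does not emulate.

## The data model

A `community_table` holds non-negative integer counts (taxa × samples)
with one lineage string per taxon; counts are stored as integers and
relative abundances are always derived on demand, never persisted, so a
table cannot be accidentally double-normalised. Per-sample metadata (site,
depth, layer labels, Tp, PWC, pH, Eh, POM, TN, POCD, ALT, MAGT) live in a
validated `sample_frame`: depths strictly increase within a site, and
sub-layer labels (TAL, SAL, FFL, TPL, SPL) must be consistent with the
active/permafrost main-layer split. Because the frozen fringe layer (FFL)
straddles the thaw front, FFL samples carry an explicit per-sample
main-layer flag rather than inheriting one from the label.

Threshold comparisons are inclusive (`>=`/`<=`) throughout the package,
with two deliberate exceptions that follow the field's stated
conventions: core-taxon occupancy must *exceed* 70 % (strict `>`), and
network edges must *exceed* the correlation threshold (strict `>`, e.g.
r > 0.35).

## Rarefaction and filtering

`rarefy()` subsamples each sample's reads without replacement to a common
depth (default: the minimum column sum). The subsampler is a direct
vectorised hypergeometric draw; the test suite checks it against the
closed-form hypergeometric expectation over 250 seeds. The standard
noise filter drops taxa whose mean relative abundance is below 0.01 %
(`min_mean_rel = 1e-4`), inclusive at the boundary.

## Null-model stochasticity ratio

For a group of samples, null communities preserve each sample's richness
and total count; taxa are drawn with probability proportional to their
occurrence frequency in the group pool, and abundance is re-allocated
across the drawn taxa in proportion to pooled abundance. The default
allocation draws the total as individuals (one multinomial draw over the
pooled proportions). A deterministic largest-remainder variant
(`allocation = "proportional"`) is available, but it produces a null
ensemble with no sampling variance: genuinely stochastic communities then
look *more* variable than their own null and the ratio collapses toward
0.5 from above. The individual-based draw is the variant under which the
boundary-at-0.5 reading of the ratio is calibrated, which is why it is
the default.

Per within-group pair, with observed similarity `C = 1 − BC` and null
expectation `E`:

* if `C >= E` (communities more similar than chance — selection toward a
  shared optimum) the ratio is `E / C`;
* otherwise (communities more divergent than chance) it is
  `(1 − E) / (1 − C)`.

Both branches live in [0, 1] up to sampling noise and are clamped; the
unclamped values are kept in `raw_ratios` for audit. The group value is
the mean over pairs: above 0.5 means assembly is predominantly
stochastic, below 0.5 predominantly deterministic. A pair with zero
observed similarity but nonzero null expectation is scored 1 (maximal
stochasticity) with a warning.

## Sloan neutral community model

Occupancy is modelled as `1 − pbeta(d; Nm·p, Nm(1−p))`, with `p` a
taxon's mean relative abundance and `d` the detection limit
(`1 / mean reads per sample` unless overridden). `Nm` is fitted by
unweighted nonlinear least squares on the unbinned per-taxon points
(`minpack.lm::nlsLM`, bounded in `[1e-3, 1e9]`, up to 500 iterations);
binning and weighting were deliberately avoided as the simplest faithful
reading of the occupancy-abundance fit. `R² = 1 − SSE/SST` may be
negative for non-neutral data and is reported as such. A fitted migration
rate above 1 is reported with a flag rather than truncated.

## Modified Mantel test

Community distance is regressed against the pairwise Euclidean distance
of one environmental variable under four candidate forms — `Y~X`,
`Y~ln(X)`, `ln(Y)~X`, `ln(Y)~ln(X)` — and the form with maximal |r| wins;
ties go to the earlier (simpler) form. Before any log, a variable with
zeros or negatives is shifted by its minimum, and zeros surviving the
shift are replaced by 0.05 × the minimum positive value (−3.00 in natural
log when that minimum is 1); the applied shift and replacement are
returned in an audit record. Significance uses sample-label permutation
of the environmental variable. By default the four-model selection is
re-run inside every permutation: selecting by max |r| and then permuting
only the chosen form is anti-conservative under the null, and the
re-selecting permutation restores a uniform null p (verified by KS
calibration in the tests). `perm_refit = FALSE` gives the
fixed-transformation variant.

## SparCC and networks

`sparcc_correlations()` implements the log-ratio variance procedure:
T_ij = var(ln(x_i/x_j)) across samples, averaged over `n_inner` Dirichlet
resamples of each sample's composition (counts + pseudocount 1); basis
variances solve the linear system obtained by summing T over included
partners; correlations follow as
`(ω_i² + ω_j² − T_ij) / (2 ω_i ω_j)`, clipped to [−1, 1]. The single most
correlated pair above `exclusion_threshold` (default 0.1) is excluded and
the system re-solved, up to `n_iterations` (default 10) rounds; a taxon is
never stripped below three partners. Defaults (`n_inner = 20`,
pseudocount 1, `n_boot = 99` for pseudo-p-values) are desk-scale choices.
`n_inner = 0` switches to posterior-mean fractions, making the estimate
deterministic — the leave-one-out single-sample machinery uses this
because its pseudovalue `N·ρ − (N−1)·ρ₋ₛ` amplifies any resampling noise
N-fold. Pseudo-p-values shuffle each taxon's counts across samples
independently; two-sided p = (1 + hits) / (1 + n_boot).

Networks keep pairs with |rho| strictly above the threshold and p
strictly below 0.05 (presets: 0.35 for layer-level, 0.65 for site-level
comparisons). Isolated nodes are dropped so density and degree describe
the connected vocabulary; the pre-threshold node count is retained.
Modularity uses deterministic greedy modularity maximisation;
eigenvector centrality is computed on the largest component. Natural
connectivity is `ln(mean(exp(λ_i)))` over adjacency eigenvalues (log-sum-
exp stabilised); an edgeless graph scores exactly 0. Robustness curves
remove `round(f·E)` edges uniformly at random (targeted attack is not the
default because random attack is the comparison convention here),
averaging over replicates. When groups differ in size, the two
adjacent-depth samples with the smallest gap are averaged (rounded mean
counts, mean depth) until sizes match, keeping networks comparable.

The "single-sample network" construction is a declared stand-in built
from the linear leave-one-out perturbation above; it is validated against
internal-consistency properties (duplicate-sample symmetry, homogeneity
under i.i.d. data, detection of a planted sample-specific dependence),
not against an external reference implementation.

## Stability, core taxa, degradation, carbon

AVD is computed on relative abundances so read-depth differences cannot
masquerade as instability. Within each reference group, taxa with zero
standard deviation are excluded from the average; a group of identical
samples gets AVD 0 and stability 1 with a flag. "Standardised" AVD is
min–max over the analysis set by default (stability in [0, 1]); z-scoring
is available, and the choice is recorded in the output because the
convention is not universal.

Core taxa are the intersection of the top 5 % of taxa by mean relative
abundance (rank ties broken by taxon id) and occupancy strictly above
70 %. The degradation index is PC1 of z-standardised ALT and MAGT,
sign-fixed so that larger PDI means thicker active layer (more degraded).
Species trends filter at 0.01 % mean abundance, rank Spearman |r| against
the gradient, and BH-adjust. Group comparisons run Kruskal–Wallis plus
BH-adjusted pairwise Wilcoxon tests, with compact letters assigned by a
greedy insert-absorb pass in deterministic label order.

The stability–POCD association replaces a random-intercept mixed model
with a fixed-effect stratum adjustment (one indicator per site or
sub-layer) and within-stratum permutation of the stability values; at
these group counts the estimand is the same and every step is directly
testable. Singleton strata are merged into the nearest level with a flag.

## The synthetic generator

`simulation_config()` defaults encode the profile design the pipeline
targets: 5 sites × 25 depths to 15 m (125 samples), a 300-taxon
log-normal metacommunity, 20 000 reads per sample. Environmental
covariates decay (Tp, PWC, POM, TN) or rise (pH) with depth with Gaussian
noise at 5 % of each range; ALT and MAGT increase with site index so the
degradation ordering is built in. Each sample's expected composition is
`α·w(E) + (1−α)·π`, where `w(E)` is a Gaussian niche response on a single
standardised depth axis (breadth σ_niche = 0.15 by default; the
covariates are strongly collinear with depth, so one axis carries the
ground truth) and `π` is drawn from the stationary law of Wright–Fisher
drift with immigration — Dirichlet with concentration
`Nm = m_true × reads_per_sample` — which is exactly the local-community
model the NCM module fits, making `m_true` recoverable ground truth.
Defaults α = 0.6 (active) and 0.25 (permafrost) express stronger niche
selection where seasonal thaw operates. Counts are
Dirichlet-multinomial with θ = 20 000 (mild technical overdispersion,
roughly doubling multinomial variance at the default depth). Core taxa
(5 % of the pool) get uniformly high metacommunity weight, which keeps
their occupancy above 70 % by construction. POCD is a depth baseline
`2 + 6·exp(−depth/0.4)` — steep decline through the near-surface organic
horizon, near-constant below, the canonical permafrost carbon profile —
plus `slope × stability` (default −1) and Gaussian noise (sd 0.5). For
the strong-filtering validation condition, "narrow niches" is fixed at
σ_niche = 0.05, the narrow end of realistic depth-niche breadths.

What the generator does **not** emulate: phylogenetic structure, archaea/
fungi/viruses, gene content, spatial autocorrelation between neighbouring
cores, seasonal dynamics, and compositional biases of extraction or
sequencing. Passing tests therefore demonstrate that the estimators
recover truth under a faithful but idealised assembly model — not that
any particular field dataset satisfies that model.

## Problem sizes and numerical choices

The test and validation runs use deliberately modest sizes chosen to make
Monte-Carlo properties stable: regime separation uses 20 seeds per regime
(2 × 12-sample profiles, 80 taxa, 30 nulls); NCM recovery simulates 300
taxa × 100 samples from the fitted model itself; the SparCC oracle plants
a 0.8 log-scale correlation among 48 independent taxa at n = 200;
robustness monotonicity averages 100 replicate attacks; sign recovery of
the stability–carbon slope uses 100 generator seeds at the full default
design; permutation calibrations use 200 null datasets each. Degenerate
inputs follow explicit conventions rather than silent coercion: all-zero
samples error in Bray–Curtis and relative abundance; an edgeless network
reports zero topology with a flag; degenerate occupancies abort the NCM
fit; constant predictors are skipped and flagged in driver tables.
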