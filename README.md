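# permacomm

Microbial community ecology along permafrost depth profiles: assembly
processes, co-occurrence networks, community stability, and their link to
soil organic carbon storage.

Deep permafrost cores yield taxa-by-sample count tables spanning the
seasonally thawed **active layer** and the perennially frozen **permafrost
layer**, sampled at sites that differ in how degraded the permafrost is.
`permacomm` implements the full inference chain such profile studies use,
as composable R functions plus a one-config pipeline, and pairs it with a
synthetic profile generator whose assembly regime, core-taxon structure
and stability–carbon link are known ground truth — so every stage can be
validated, not just run.

## What it computes

* **Diversity & ordination** — richness, Shannon `H = -Σ p ln p`,
  Bray–Curtis `BC(x,y) = Σ|x−y| / Σ(x+y)`, PCoA, PERMANOVA,
  β-dispersion (distance to group centroid), distance-decay fits.
* **Assembly processes** —
  * *Stochasticity ratio*: richness-preserving, occurrence-frequency-
    proportional null communities; per sample pair the ratio of expected
    to observed similarity (or dissimilarity, whichever regime applies),
    clamped to [0, 1]. Values above 0.5 indicate predominantly stochastic
    assembly, below 0.5 predominantly deterministic.
  * *Sloan neutral community model*: occupancy(p) =
    `1 − Beta CDF(d; Nm·p, Nm(1−p))` fitted by nonlinear least squares;
    reports `Nm`, migration rate `m = Nm/N`, and R².
  * *Levins niche overlap* `O_jk = Σ p_ij p_ik / Σ p_ij²` (symmetrised).
  * *Modified Mantel test*: best of `Y~X`, `Y~ln(X)`, `ln(Y)~X`,
    `ln(Y)~ln(X)` by |r|, permutation inference, with the
    shift-then-replace-zeros (0.05 × minimum positive) log convention.
* **SparCC networks** — log-ratio-variance basis correlations with
  iterative strong-pair exclusion, permutation pseudo-p-values,
  thresholded graphs (presets r > 0.35 for layers, r > 0.65 for sites,
  p < 0.05), topology (density, transitivity, modularity, eigenvector
  centrality, linkage density), natural connectivity
  `NC = ln(mean(exp(λ_i)))`, edge-attack robustness curves, depth-adjacent
  sample averaging for equal group sizes, leave-one-out single-sample
  networks, and core/other edge analytics.
* **Stability & core taxa** — AVD (average variation degree)
  `AVD_s = mean_i |x_is − μ_i| / σ_i`; stability = 1 − min–max-standardised
  AVD; core taxa = top 5 % by mean relative abundance occurring in > 70 %
  of samples; Spearman driver surfaces with BH correction.
* **Degradation & carbon** — PDI (PC1 of standardised active-layer
  thickness and mean annual ground temperature), species trend analysis
  (0.01 % abundance filter, Spearman |r| ranking), Kruskal–Wallis group
  comparisons with BH-adjusted pairwise letters, POCD percent change along
  the gradient, and the stratum-adjusted regression of POCD on community
  stability with within-stratum permutation inference.

## Worked example

```r
library(permacomm)

cfg <- simulation_config(n_sites = 3, depths_per_site = 10,
                         species_pool_size = 60, reads_per_sample = 1500,
                         seed = 42)
ds  <- simulate_dataset(cfg)          # table + metadata + ground truth
tab <- rarefy(ds$table, seed = 1)     # even depth = min column sum

perm <- subset_table(tab, samples = ds$frame$main_layer == "permafrost",
                     drop_zero = TRUE)
stochasticity_ratio(perm, n_null = 50, seed = 2)
#> stochasticity ratio: 0.7281 ( 276 pairs, 50 nulls )
#>   regime: more stochastic (> 0.5)

fit_neutral_model(tab)
#> Sloan neutral community model fit
#>   Nm = 304.9  m = 0.2032  R2 = 0.862  (d = 0.000667, 60 taxa)

identify_core_taxa(tab)
#> core_taxa_set: 3 taxa (top 5% abundance, occupancy > 70% )

stab  <- avd_stability(tab, ds$frame$main_layer)
assoc <- stability_pocd_association(stab, ds$frame, ds$frame$sub_layer,
                                    seed = 3)
#> stability-POCD coefficient: -1.704 (partial r = -0.523, p = 0.003)
```

Reading the output: the permafrost-layer stochasticity ratio 0.73 sits
above the 0.5 boundary, as expected under the generator's weakly
selective deep-layer regime (`alpha_permafrost = 0.25`). The fitted
migration rate (0.20) exceeds the generator's `m_true = 0.1` because the
default dataset mixes niche filtering into the active layer; on pure
`alpha = 0` data the fit recovers `m_true` within ~10 %. The
stability–POCD coefficient is negative, matching the generator's
`pocd_stability_slope = -1` (attenuation and spread reflect the noisy,
36-sample demo). The whole chain, networks included, runs from one config
via `run_pipeline(pipeline_config(...))`, which writes TSV outputs plus a
checksummed manifest.

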