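# riverlake

Tools for analysing **microbial community assembly along river–lake
continua** from amplicon sequence variant (ASV) count tables. The package
is aimed at aquatic microbial ecologists who want, in one place, the
standard battery used to ask *"is this community assembled by deterministic
(niche) or stochastic (neutral) processes, and what structures it in
space?"*:

- **α/β-diversity** — richness, Chao1 (`S + F₁²/2F₂`), Shannon
  (−Σ pᵢ ln pᵢ), Gini–Simpson (1 − Σ pᵢ²); Kruskal–Wallis group tests with
  Dunn/BH letters; Bray–Curtis (`Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ)`), PCoA, one-factor
  PERMANOVA.
- **Species-abundance distributions** — rank-abundance and normalised
  (NRAD) curves, octave binning, and maximum-likelihood fits of four SAD
  models with AIC ranking and Kolmogorov–Smirnov rejection: broken stick
  `E(nᵢ) = (N/S) Σ_{x=i}^{S} 1/x`, geometric series `E(nᵢ) ∝ k(1−k)^{i−1}`,
  the Volkov neutral sampling formula (parameters θ, m, evaluated by
  Gauss–Legendre quadrature in log-gamma space), and the zero-truncated
  Poisson-lognormal (μ, σ_ln, Gauss–Hermite quadrature).
- **Null-model stochasticity ratio** — constraint-preserving randomisation
  (per-sample richness and totals fixed; taxa drawn ∝ occurrence
  frequency, reads allocated ∝ regional relative abundance) with the
  similarity-ratio statistic `ST = min(C, Ē)/max(C, Ē)` averaged per
  habitat, plus PERMANOVA of the observed pseudo-F against the null
  ensemble.
- **Spatial/environmental structure** — haversine distances,
  distance-decay and Mantel tests, PCNM spatial eigenfunctions (MST
  truncation, 4t replacement), forward selection with the double stopping
  rule, CCA (via vegan), and environment/space variation partitioning with
  Ezekiel-adjusted R² fractions a/b/c/d.
- **Co-occurrence networks** — abundant-and-frequent taxon filtering
  (> 0.05 % mean relative abundance, > 50 % occurrence), Pearson
  correlations, random-matrix-theory thresholding (eigenvalue
  nearest-neighbour spacings tested Poisson vs Wigner–Dyson), fast-greedy
  modularity, the Table-style topology panel (N, E±, avgCC, APL, ND,
  AD = 2E/N, GD = 2E/N(N−1)), zi/Pi node roles (cutlines 2.5 / 0.62), and
  the small-world coefficient `σ = (avgCC/avgCC_r)/(APL/APL_r)` against an
  Erdős–Rényi G(N, E) ensemble.
- **Synthetic communities** — seeded generators for lognormal regional
  pools, Hubbell-style neutral sampling with immigration `m`,
  Gaussian-niche filtering along a spatially autocorrelated gradient
  (a salinity analogue), and planted correlation blocks, so every stage is
  testable without sequencing data.

## Worked example

```r
library(riverlake)

# a shared regional pool, a dispersal-assembled "river" and a
# niche-filtered "lake"
pool  <- simulate_metacommunity(S = 400, log_sd = 1.5, seed = 42)
river <- simulate_neutral_samples(pool,
  simulation_scenario("neutral", n_samples = 10, J = 5000, m = 0.3, seed = 1))
lake  <- simulate_niche_samples(pool,
  simulation_scenario("niche", n_samples = 10, J = 5000,
                      niche_breadth = 0.4, seed = 2))

river$table
#> count_table: 10 samples x 400 taxa, 50,000 reads

head(alpha_diversity(river$table), 3)
#>   sample_id richness    chao1  shannon   simpson
#> 1       S01      305 325.1324 4.922383 0.9861959
#> 2       S02      309 327.0000 4.866237 0.9843790
#> 3       S03      306 325.5135 4.930113 0.9866222

# SAD model selection on the pooled river community
ra   <- rank_abundance(river$table)
fits <- lapply(c("BS", "GS", "Volkov", "PLN"), function(m) fit_sad(ra, m))
print(compare_models(fits, ra), digits = 3)
#>    model n_params  logLik     AIC   ks_D     ks_p ks_rejected    dAIC
#> 1    PLN        2   -36.6    77.2 0.0477 3.34e-01       FALSE     0.0
#> 2 Volkov        2   -58.0   120.0 0.1161 5.12e-05        TRUE    42.9
#> 3     GS        1 -6289.7 12581.4 0.1480 7.03e-08        TRUE 12504.3
#> 4     BS        0 -8483.7 16967.3 0.2245 1.39e-17        TRUE 16890.2
```

The Poisson-lognormal wins by a wide AIC margin and is the only model not
rejected by the K-S test — the usual outcome for microbial SADs.

```r
stochasticity_ratio(river$table, rep("river", 10), n_iter = 300, seed = 3)
#> river: SR = 98.8% +/- 0.9% (45 pairs)
stochasticity_ratio(lake$table,  rep("lake", 10),  n_iter = 300, seed = 3)
#> lake: SR = 47.5% +/- 37.5% (45 pairs)
```

The dispersal-assembled river community is indistinguishable from its null
expectation (SR ≈ 100 %), while niche filtering pulls the lake far below
it — the qualitative river > lake ordering expected when salinity-like
filtering dominates lake assembly.

```r
# small-world coefficient from a printed topology panel
signif(small_world_sigma(avgCC = 0.376, APL = 7.07,
                         avgCC_r = 0.056, APL_r = 3.33), 2)
#> [1] 3.2
```

The full pipeline (filter → rarefy → diversity → SAD → stochasticity →
spatial → network, with a consolidated `report.txt`) runs from one
configuration:

```r
run_pipeline(default_pipeline_config(out_dir = "demo_run", seed = 1))
```

A command-line front end with `simulate`, `alpha`, `beta`, `sad`,
`stochasticity`, `spatial`, `network` and `run-all` subcommands is
installed at `system.file("cli", "riverlake", package = "riverlake")`.

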