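---
title: "Methods: diversity, SAD models, null-model stochasticity, spatial partitioning and co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community assembly along river-lake continua}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverlake)
```

This vignette documents the models, the numerical choices and the design
decisions behind `riverlake`, in the spirit of the methods sections of the
established community-ecology packages. It states no empirical result that
the test suite does not itself compute.

## The scientific question

Along a river–lake continuum, local microbial communities can be assembled
by *stochastic* processes (dispersal, drift, chance colonisation) or by
*deterministic* niche processes (environmental filtering — typically by a
salinity-like gradient — and biotic interactions). The package implements
the standard battery used to separate the two: diversity contrasts,
species-abundance-distribution (SAD) model selection, null-model
stochasticity ratios, spatial/environmental variation partitioning, and
co-occurrence network topology.

## Data model and preprocessing

A `count_table` is a samples × taxa matrix of non-negative integer read
counts (ASVs), optionally with ranked lineages. Preprocessing follows the
usual amplicon conventions:

* **Taxon filter** (`filter_min_abundance`): taxa with pooled count
  strictly below `min_total = 10` are dropped — the common cutoff for
  unreliable unique sequences. Samples emptied by the filter are kept but
  flagged; downstream operations reject all-zero samples explicitly.
* **Rarefaction** (`rarefy`): subsampling *without replacement*
  (multivariate hypergeometric per sample). The literature often says only
  "randomly selected a subset"; without-replacement matches subsampling of
  physical reads and is what the hypergeometric oracle in the test suite
  checks. The pipeline orders filter → rarefy and writes both tables, since
  published workflows are usually ambiguous on the order.
* **Orientation**: taxa are columns internally; readers accept either
  orientation via a flag or auto-detect it by matching ids against the
  metadata. A BIOM (JSON) reader is provided for interoperability.

## Alpha and beta diversity

Richness, Chao1, Shannon (natural log) and Simpson are computed per
sample. Two deliberately documented defaults:

* **Simpson is Gini–Simpson** (1 − Σp²), bounded in [0, 1]; the inverse
  form is behind a flag. Papers rarely name the variant; the bounded form
  matches the axis range of the usual box plots.
* **Chao1 is the classic estimator** S + F₁²/(2F₂), with the
  S + F₁(F₁−1)/2 fallback when F₂ = 0; the bias-corrected form is behind a
  flag.

Group differences use Kruskal–Wallis with tie correction; the post-hoc
letters come from Dunn's z on mean ranks with Benjamini–Hochberg
adjustment (the published figures show letters but almost never name the
post-hoc procedure; Dunn/BH is the defensible default). With 3 samples per
group only the extreme contrast can survive BH adjustment — the tests
assert exactly that, not three distinct letters.

Bray–Curtis is the β-diversity workhorse; it is symmetric with zero
self-distance but **not metric**, so PCoA (Gower double-centering +
eigendecomposition) will produce negative eigenvalues on real data. The
default is to *report* them (count and total magnitude) and compute axis
proportions over the positive eigenvalues only; Cailliez correction is
optional. PERMANOVA uses the one-factor pseudo-F on squared distances with
`p = (1 + #{F_perm ≥ F_obs}) / (1 + n_perm)`; with group sizes of six the
label permutation that recreates the observed split (or its complement)
recurs often enough that p ≤ 0.001 is unattainable at 999 permutations —
power examples in the tests therefore use eight samples per group.

## SAD models

Four models are fitted to a pooled rank-abundance vector:

| model  | params | expected value | fitted on |
|--------|--------|----------------|-----------|
| broken stick (BS) | 0 | E(nᵢ) = (N/S) Σ_{x=i}^S 1/x | ranks |
| geometric series (GS) | k | E(nᵢ) ∝ k(1−k)^{i−1} | ranks |
| Volkov neutral | θ, m | sampling formula for ⟨φₙ⟩ | octaves |
| Poisson-lognormal (PLN) | μ, σ_ln | zero-truncated mixture | octaves |

Design decisions:

* **Rank-based fits (BS/GS) use a Poisson likelihood around the expected
  rank abundances** — the standard RAD-fitting convention, which gives
  comparable AICs between the two.
* **Volkov and PLN are fitted on octave (doubling abundance class)
  frequencies** with a Poisson likelihood per octave, because these models
  predict species-per-abundance, not per-rank values. Octave j holds
  abundances in [2ʲ, 2ʲ⁺¹).
* **Volkov integration**: the neutral sampling formula is integrated over
  [0, γ], γ = m(J−1)/(1−m), by 160-node Gauss–Legendre quadrature with all
  summands assembled in log-gamma space (J can be in the hundreds of
  thousands); θ and m are estimated from a 5×5 coarse grid over
  (log θ, logit m) refined by Nelder–Mead.
* **PLN** uses 40-node Gauss–Hermite quadrature over the lognormal mixing
  density and is zero-truncated at the veil line n ≥ 1 (untruncated
  variant behind a flag). Wide octaves are summed on a log-spaced integer
  grid with trapezoidal weights, which keeps a likelihood evaluation at
  sub-millisecond cost without visible bias at the tested scales
  (parameter recovery within ±0.15 at S = 1000).
* **K-S goodness of fit** compares the empirical abundance CDF with the
  model CDF (parametric for Volkov/PLN, the CDF of predicted rank
  abundances for BS/GS). The abundance axis is discrete, so the asymptotic
  one-sample p-value is approximate; the result carries an explicit
  `approximate = TRUE` flag.
* Model ranking is by AIC = 2k − 2 logLik with ΔAIC and K-S rejection
  flags. NRAD normalisation (reduction of every curve to a common species
  count) is by repeated random species subsampling without replacement,
  re-sorting and renormalising; the exact algorithm of the original NRAD
  software is unspecified, so this subsampling scheme is this package's
  documented definition.

## Null-model stochasticity ratio

The null ensemble preserves, for every sample, its **richness** and its
**total reads**; taxon identities are drawn without replacement with
probability proportional to regional occurrence frequency, and reads are
allocated to the chosen taxa by a multinomial draw proportional to
regional relative abundance (each chosen taxon keeps at least one read so
richness is exact). Published descriptions of "abundance-based null
models" rarely pin down the constraint set; this one is declared in the
output metadata and validated in the tests by an independent re-implementation
of the sampling scheme.

The pairwise statistic is the **similarity-ratio** form
ST = min(C, Ē)/max(C, Ē) with C = 1 − BC the observed similarity and Ē the
ensemble mean — matching the widely used code lineage; the
dissimilarity-side normalisation is available via `side =
"dissimilarity"`. Group SR is the mean (×100 %) ± sd over within-group
pairs. Pairs with zero observed similarity and positive expectation are
excluded with a warning (the ratio is undefined there). Significance
against the ensemble uses PERMANOVA of the observed pseudo-F versus the
null F distribution. Defaults: 1000 iterations.

What a green test establishes: on data *drawn by the null generator
itself* SR ≥ 85 %, and neutral synthetic data score higher than
niche-filtered data at matched S, J and n in ≥ 9/10 seeds. It does **not**
establish the published habitat percentages, which depend on the deposited
reads.

## Spatial and environmental structure

* Geographic distances are haversine on a sphere of radius 6371.0088 km,
  used directly (no projection): at catchment scale (~1°) curvature error
  is negligible and no CRS dependency is introduced.
* **PCNM**: truncation t = largest minimum-spanning-tree edge (Prim's
  algorithm), distances > t replaced by 4t, PCoA of the truncated matrix,
  positive-eigenvalue eigenvectors retained. Duplicate coordinates (zero
  distances) are rejected — they would undermine the truncation logic.
* **Forward selection** is greedy on RDA R² with the double stopping rule
  (per-step Freedman–Lane residual-permutation p ≤ α **and** cumulative
  adjusted R² not exceeding the global model's). The known conservative
  quirk of the rule — a strong first candidate can exceed the global
  adjusted R² when the remaining candidates are noise — is accepted as
  designed behaviour.
* **Variation partitioning** uses Hellinger-transformed counts as the
  community response (published pRDA workflows square-root transform the
  *environmental* predictors but rarely state the community transform;
  Hellinger is the standard choice for RDA on abundances and is
  configurable). Environmental predictors are square-root transformed in
  the pipeline. R² values are Ezekiel-adjusted; fractions a (pure
  environment), b (shared), c (pure space), d (unexplained) may be
  slightly negative and are reported as-is, clamped to zero only in the
  human-readable report. The linear coordinate trend is included with the
  spatial fraction, and spatial predictors (PCNM + trend) are themselves
  forward-selected in the pipeline.
* **CCA** wraps vegan (log(1+y) transformed counts, chi-square
  standardisation under row weights) with a 999-permutation ANOVA and each
  variable's *sole* explained inertia. A constant predictor yields zero
  constrained inertia (vegan aliases it); genuinely rank-deficient
  predictor sets are an error.

## Co-occurrence networks

Taxa are pre-filtered to the abundant and frequent set (mean relative
abundance strictly > 0.05 %, occurrence strictly > 50 %). Pearson
correlations are computed on relative abundances (log(1+x) counts behind a
flag). The |r| threshold is chosen by random-matrix theory: for each
candidate, entries below it are zeroed, the eigenvalue spectrum is
unfolded by a smooth cubic fit of the cumulative spectral function, and
the nearest-neighbour spacing distribution is tested against the Poisson
law by chi-square on 20 bins at α = 0.05; the chosen threshold is the
lowest candidate where Poisson is not rejected, with a prominent fallback
to a fixed threshold when the scan fails (small matrices often leave too
few eigenvalues for the spacing test). These constants are configurable
because published pipelines delegate them to an online service whose
internals are not recoverable.

Topology: average local clustering coefficient over all nodes (degree < 2
contributes 0), average path length and diameter on the **largest
connected component** (sparse river-type networks are usually
disconnected; per-component values are also emitted), AD = 2E/N,
GD = 2E/(N(N−1)), fast-greedy (CNM) modularity. Node roles use the within-
module degree z-score zi (0 when the module sd is 0) and participation
coefficient Pi = 1 − Σ(k_is/k_i)² with the canonical 2.5 / 0.62 cutlines.
The small-world coefficient σ = (avgCC/avgCC_r)/(APL/APL_r) is computed
against 100 Erdős–Rényi G(N, E) graphs with matched node and edge counts;
`small_world_sigma()` is exposed as a pure function so printed topology
panels can be re-checked directly.

## Synthetic communities: what they emulate, and what they do not

The generators provide *known assembly regimes*:

* `simulate_metacommunity`: lognormal regional pool (the standard
  microbial SAD assumption), parameters S and σ of log abundance.
* `simulate_neutral_samples`: one-shot composite sampling — a
  Dirichlet-perturbed pool with concentration I = m(J−1)/(1−m) followed by
  a multinomial draw of J reads — rather than generation-by-generation
  drift. This preserves the two limits the tests rely on (m → 1 gives
  i.i.d. multinomial sampling; J → ∞ recovers the pool) at desk-scale
  speed. Default J = 25000 so tables resemble a rarefied amplicon table.
* `simulate_niche_samples`: Gaussian taxon responses to a spatially
  autocorrelated gradient (Gaussian-kernel-smoothed white noise along the
  transect, range in km) — a salinity analogue written to the metadata as
  `gradient`. Narrow breadth gives strong turnover; breadth → ∞ approaches
  the neutral m = 1 limit, which the tests verify by PERMANOVA.
* `simulate_block_correlated_taxa`: latent-factor blocks with loading
  √strength, negative blocks loading negatively on the preceding positive
  factor, counts Poisson-drawn around lognormal means. The abundance noise
  default is σ_log = 0.3: at this value the count mapping is close enough
  to linear that raw-count correlations follow the Gaussian sampling null
  (the ±0.3 band at n = 100 used by the tests); note that *relative-abundance*
  correlations on small taxon panels additionally carry compositional
  closure and are not a clean read-out of the planted structure.

Not emulated: sequencing error, chimeras, taxonomy structure (placeholder
lineages only), temporal dynamics, and the actual catchment geometry. A
green synthetic test therefore establishes internal correctness and the
qualitative regime orderings, not any published dataset-level number.

## Determinism and seeds

Every stochastic operation takes an explicit seed and runs under a local
RNG (caller streams are never perturbed). The pipeline fans a master seed
out through named substreams per stage, so changing one stage's settings
does not perturb another stage's randomness, and identical configurations
reproduce byte-identical numeric outputs.

## Known limitations

* The Volkov fit assumes the pooled community size J equals the observed
  N; for very uneven pooling across samples the effective J is ill-defined.
* Octave-based likelihoods for Volkov/PLN and rank-based likelihoods for
  BS/GS are compared on one AIC scale; this follows the established
  practice but mixes data resolutions, and BS/GS AICs are accordingly
  dominated by their per-rank misfit on large-N data.
* The RMT spacing test needs enough surviving eigenvalues (≈ 25); on small
  filtered tables the scan falls back to a fixed threshold with a warning.
* The K-S p-values ignore discreteness and parameter estimation, and are
  flagged approximate.
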