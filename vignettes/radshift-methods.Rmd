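---
title: "Models and methods behind radshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind radshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`radshift` implements a comparative pipeline for climate-driven radiations:
clade diversification dynamics, rates of climate-niche evolution, the
partition of niche variation between space and phylogeny, and niche overlap
among close relatives. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic-data generator
does and does not emulate.

## Diversification

**Net rates.** `ms_rate()` is the Magallón–Sanderson method-of-moments
estimator of `r = λ − μ` from standing richness `N` and clade age `t` (MY),
under an assumed extinction fraction `ε = μ/λ`. The crown form is the
default because richness is naturally paired with crown ages; stem mode is
a flag. `ε` enters only through the survival correction: rates decrease
monotonically in `ε`, and at `ε = 0` the estimator collapses to
`ln(N/2)/t` (crown) or `ln(N)/t` (stem) — both identities are exercised to
machine precision in the tests. Nonpositive estimates are truncated at 0.

**γ and the MCCR test.** `gamma_statistic()` standardizes the internode
durations `g_k` (the time with exactly `k` lineages, `k = 2..n`, the last
measured to the present): with `T = Σ k·g_k`,

γ = [ mean over i of (Σ_{k≤i} k·g_k) − T/2 ] / [ T·√(1/(12(n−2))) ].

Under constant-rate pure birth, `k·g_k` are iid exponential, which makes γ
asymptotically standard normal; the analytic p is the lower tail. Because
incomplete sampling biases γ downward, `mccr_test()` simulates complete
pure-birth trees at the clade's true richness, prunes them uniformly to the
sampled size, and compares the observed γ to the 5th percentile of the null
(`(1 + #{γ_null ≤ γ_obs})/(1 + reps)` is the corrected p — the +1
convention keeps p away from 0). The pure-birth simulator stops just
*after* the n-th birth, at the end of a full `Exp(n·λ)` waiting interval:
only with that final interval included are the `k·g_k` iid exponential and
γ calibrated; stopping exactly at the n-th birth would bias γ positive.
MCCR replicates default to 10,000.

**Model selection.** `fit_model()` maximizes the reconstructed-process
likelihood of the branching times conditioned on the crown age and on both
crown lineages surviving, with the combinatorial constant `log((n−1)!)`
kept in every model so the six likelihoods are mutually comparable:

* `PB` — pure birth; closed-form MLE `λ̂ = (n−2)/T`.
* `BD` — constant birth–death, Nee et al. form, optimized over `(r, ε)`
  with five deterministic starts (`ε ∈ {0, .2, .5, .8, .95}`); the
  pure-birth boundary is always a candidate, so `lnL(BD) ≥ lnL(PB)` by
  construction. The fit agrees with `ape::birthdeath` to ~1e-4 in tests.
* `DDL` / `DDX` — density-dependent speciation `λ(N) = λ₀(1 − N/K)`
  (`K > n`) and `λ(N) = λ₀·N^(−x)` (`x ∈ [−1, 5]`); `λ₀` has a closed-form
  profile MLE, so only `K` (log-transformed above `n`) or `x` is searched,
  by a 60/61-point grid plus local refinement. `x = 0` and `K → ∞` are
  explicit candidates, which enforces nesting against PB numerically.
* `YULE2` / `YULE3` — piecewise-constant pure birth with 1 or 2 shifts.
  Shift times are profiled over the grid of observed branching times; an
  event falling exactly on a shift belongs to the older epoch, each
  epoch's rate is its events/lineage-time MLE, and ties between equally
  likely shifts resolve to the older one. AIC parameter counts are
  PB 1, BD 2, DDL 2, DDX 2, YULE2 3, YULE3 5 (shift times count).

`model_select()` reports `ΔAIC_RC` = (best rate-constant AIC) − (best
rate-variable AIC); positive values favor rate variation. A caution that
the package's own calibration (in the acceptance suite) quantifies: because
the shift times of the multi-rate Yule models are *profiled over
event-aligned candidates*, their likelihood gains on constant-rate data
behave like an exponential change-point scan statistic, not like a fixed
extra parameter — gains well above the AIC penalty occur regularly, and the
three-rate model frequently out-scores the two-rate model even when a
single shift is the truth. Fixed `ΔAIC_RC` cut-offs (the conventional
"close to 4") are therefore anti-conservative for this profile; users who
need a calibrated error rate should derive the threshold from pure-birth
simulations at their own tree size, which `model_select()` plus the
generator makes a three-line exercise.

## Felsens: rates of climate-niche evolution

Species' climate values are summarized as arithmetic means per variable
(`species_climate_means()`), ln-transformed, and fed through Felsenstein's
pruning algorithm (via `ape::pic`). The felsen rate is the variance of the
standardized contrasts, `β = Σc_i²/(n−1)`: the `n−1` divisor reads "PIC
variance" as the variance over the contrasts (the ML divisor `n` is a
flag). Contrasts of logs make β exactly invariant to multiplicative
rescaling of the raw variable (unit changes). Variables with legitimate
zeros (e.g. zero summer precipitation) use a configurable `log(x + offset)`
with a message when engaged, since a bare log is undefined there. Branch
lengths are in MY, so β is ln-variance per MY. Under Brownian motion,
`(n−1)·β̂/σ²` is exactly χ²(n−1) — the test suite checks this distribution
at n = 50, and mean recovery of σ² = 0.3 over 500 unit-depth trees (on
unit-depth trees the correlation-scale simulation variance and the per-MY
rate coincide, which is why the recovery study fixes crown age 1).

## Space versus phylogeny

`fit_space_phylo()` models a species trait as multivariate normal with mean
`μ·1` and covariance `σ²·V`, `V = (1−Ø)·V_λ + Ø·S`. `V_λ` is the
unit-diagonal phylogenetic correlation (shared path length / tree depth)
with off-diagonals multiplied by Pagel's λ; `S` is a unit-diagonal spatial
similarity. Both mixture components having unit diagonal keeps `V` a
correlation-like matrix for every `(λ, Ø) ∈ [0,1]²`, so Ø is directly the
share of trait structure attributable to space. The defaults for `S`
(`spatial_similarity()`) are species occurrence centroids and linear decay
`s_ij = 1 − d_ij/d_max` of great-circle distance (spherical law of cosines,
mean Earth radius 6371 km); an exponential kernel with a range parameter is
available for sensitivity analyses. λ and Ø are bounded to `[0,1]` — fits
report when a bound is active; λ > 1 ("more structure than Brownian") is
conceptually possible but not identifiable jointly with Ø on a bounded
mixture, so it is out of scope.

`μ` and `σ²` are profiled analytically by GLS (exact, fast); the `(λ, Ø)`
surface is scanned on a fixed 11×11 grid and polished with bounded
L-BFGS-B, a combination chosen for reproducibility (no random restarts). A
near-singular `V` gets a `1e-8` ridge with a warning. The reported
decomposition `λ′ = (1−Ø)λ`, `Γ = (1−Ø)(1−λ)` satisfies
`λ′ + Γ + Ø = 1` identically. With `S = NULL` the model collapses to the
standard Pagel-λ fit, which the tests verify against both an internal
1e-3 grid search and `phytools::phylosig`.

## Niche overlap

For each climate variable, environmental space is one-dimensional (the
analyses report overlap per variable; a 2-D ordination variant is a
non-goal). `occupancy()` lays `bins = 100` cells across the *background*
range (all landscape cells), estimates Gaussian-kernel densities of the
occurrences (`o`) and of the background (`f`) at the bin centers by direct
summation, and forms occupancy `z ∝ o/max(f, ε_f)` normalized to unit
mass, with `ε_f` = 1e-8 of the background mass guarding empty-background
bins. Dividing by availability makes D insensitive to how much of the
landscape offers each environment; the kernel makes it insensitive to
raster resolution. Bandwidth defaults to Silverman's rule; 100 bins and the
rule are both configurable and recorded on the result. Because bins follow
the background range and Gaussian kernels scale with the data, D is exactly
invariant to a common affine rescaling of the environmental axis.

`schoener_D()` is `1 − ½Σ|z₁ − z₂|`. `equivalency_test()` pools the two
species' values and re-partitions them at the original sizes (default 1000
pseudoreplicates); the one-tailed p is `(1 + #{D_null ≤ D_obs})/(1+reps)`
and rejection at 0.05 is read as "ecologically distinct". One numerical
choice matters here: the bandwidth rule is held *fixed* across
pseudoreplicates — every (pseudo)species of size `n_i` uses the pooled
sample's Silverman spread statistic scaled by `n_i^(−1/5)` — so the
statistic's tuning does not fluctuate under the null, and the kernel
evaluations can be precomputed once per pair (which is what makes
1000-replicate tests over hundreds of pairs affordable). The test suite
verifies the nominal level empirically (type-I error within 2–9% at
α = 0.05 over 200 same-niche pairs).

## Cross-clade statistics

`ols()` wraps ordinary least squares at degree 1 or 2 (degree 2 is fixed
for curvature-style relations, e.g. rate vs. summer-precipitation felsens)
with the overall F-test p. `mann_whitney_exact()` enumerates all
`C(n1+n2, n1)` group assignments up to a combined n of 12 (midranks under
ties, exactness flagged off since ties condition the enumeration), and
falls back to a tie-corrected, continuity-corrected normal approximation
above; one-sided p follows the observed direction, and both sidednesses are
reported because published p-values often leave the convention implicit.

## The synthetic-data generator

The generator produces data with exactly the statistical structure the
estimators assume: `simulate_bd_tree()` (forward birth–death conditioned on
tip count, extinct lineages pruned), `prune_random()` (uniform tip
sampling), `simulate_trait()` (one MVN draw with covariance
`σ²[(1−w_s)V_λ + w_s·S]`, so the mixing weight `w_s` maps one-to-one onto
the Ø estimand), `simulate_landscape()` (an abstract rectangle in degrees
with linear gradients plus a smooth low-frequency cosine noise field — not
a map of any real region), and `simulate_occurrences()` (cells sampled
proportionally to Gaussian suitability around species optima).
`radiating_clade_scenario()` wires these into a 16-species clade with a
10-MY crown, optima evenly spaced along a summer-precipitation gradient
(niche breadth 40 on a 50–600 range) against a gradient-free control
variable with small random optimum scatter — which yields the qualitative
triad the pipeline targets: faster felsens, lower overlap and higher Ø on
the gradient variable.

What the generator does *not* emulate — and hence what passing tests do not
certify about field data: spatial sampling bias and heterogeneous effort,
measurement error in climate layers, range dynamics through time,
non-Brownian trait evolution (OU, early bursts), and spatial structure
that differs from the similarity kernel used in fitting (a misspecified
exponential-kernel variant is provided for exactly that sensitivity check).

## Problem sizes, determinism, degenerate inputs

Every stochastic routine takes a `seed` and is bit-reproducible given it;
the pipeline manifest records config and seeds so reruns are byte-identical.
The test and acceptance workloads use the scales at which the statistical
claims are stated: 1000 pure-birth trees (n = 50) for γ calibration, 10,000
MCCR replicates, 500 Brownian replicates for felsen recovery, 100 fits per
regime (n = 64) for Ø recovery, 200 trees for likelihood-nesting and
ΔAIC calibration, and 200 species pairs × 1000 pseudoreplicates for the
equivalency level check.

Degenerate inputs are handled explicitly rather than silently: trees must
be ultrametric within `1e-6 ×` depth (rate-smoothed chronograms are only
numerically ultrametric); polytomies are resolved to zero-length
bifurcations with a warning; species with fewer than 3 records skip outlier
cleaning (the rule is distance to the median center beyond
`median + k·MAD`, raw MAD, `k = 5` by default — deterministic and reported,
where "clearly beyond the distribution" needs an operational definition);
zero-variance occurrence sets collapse to a spike profile with a warning;
coincident-species spatial matrices are rejected as degenerate; optimizer
non-convergence is an error, never a silent NA.
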