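# radshift

Comparative-phylogenetics tools for asking whether a clade's radiation
tracks the establishment of new climate gradients — the situation of the
Cape Floristic Region's winter-rainfall flora, where lineages that could
evolve their climate preferences quickly are thought to have diversified
fastest along newly formed precipitation gradients.

Given a time-calibrated phylogeny, species occurrence records and a gridded
climate landscape, `radshift` computes, per clade:

* **Net diversification rates** `r = λ − μ` from standing richness `N` and
  crown age `t` (Magallón–Sanderson estimator), at assumed extinction
  fractions ε = μ/λ; at ε = 0 the crown form reduces to `ln(N/2)/t`.
* **The γ statistic** of internode spacing (negative γ = branching
  concentrated early, i.e. a diversification slowdown), its analytic
  one-tailed normal p, and an **MCCR test** that corrects γ for incomplete
  sampling by simulating complete pure-birth trees and pruning them to the
  sampled size.
* **Diversification model selection** by AIC among rate-constant models
  (pure birth; birth–death, Nee et al. likelihood) and rate-variable models
  (linear and exponential density dependence; two- and three-rate Yule with
  profiled shift times), summarized as `ΔAIC_RC = AIC_RC − AIC_RV`.
* **Rates of climate-niche evolution in felsens**: the variance of
  standardized phylogenetically independent contrasts of ln-transformed
  species climate means — one felsen is one unit of ln-trait variance per
  million years.
* **Space vs. phylogeny decomposition**: a joint ML fit of trait covariance
  `σ²[(1−Ø)·V_λ + Ø·S]`, where `V_λ` is the Pagel-λ phylogenetic
  correlation and `S` a spatial similarity from occurrence centroids.
  Reported as Ø (0 = only phylogeny, 1 = only space), `λ′ = (1−Ø)λ`
  (space-corrected phylogenetic signal) and `Γ = (1−Ø)(1−λ)` (neither).
* **Niche overlap**: background-corrected kernel occupancy profiles per
  climate variable, Schoener's `D = 1 − ½Σ|z₁−z₂|` (0 = disjoint,
  1 = identical), and a permutation **equivalency test** that pools and
  re-splits the two species' occurrences.
* **Cross-clade statistics**: OLS/polynomial regressions among rates,
  felsens, overlap and Ø, and an exact Mann–Whitney U test.

A synthetic-data generator (birth–death trees, traits with tunable
phylogenetic and spatial signal, gradient landscapes, suitability-sampled
occurrences) makes every stage testable without external data.

## Worked example

The bundled scenario generates a 16-species clade whose species partition a
summer-precipitation (SPP) gradient while sharing preferences on a
gradient-free control variable (CTRL):

```r
library(radshift)
sc  <- radiating_clade_scenario(n_species = 16, n_points = 60, seed = 42)
occ <- clean_outliers(sc$occ)

diversification_table(sc$tree, sc$clades, mccr_reps = 2000, seed = 42)
#>   clade  N  t  mode   r_0 r_0.5 r_0.99 n_sampled obs_gamma p_gamma
#> 1    R1 16 10 crown 0.208 0.185 0.0135        16     -1.21   0.112
#>   critical_gamma obs_minus_critical p_mccr
#> 1           -1.6              0.387  0.109

model_select(branching_times(sc$tree))
#>  model class        lnL k      AIC
#>     PB    RC -10.733449 1 23.46690
#>     BD    RC -10.733449 2 25.46690
#>    DDL    RV  -9.287876 2 22.57575
#>    DDX    RV  -9.204531 2 22.40906
#>  YULE2    RV  -8.946472 3 23.89294
#>  YULE3    RV  -6.287684 5 22.57537
#> delta AIC_RC (best RC PB - best RV DDX) = 1.058
#> rate constancy not rejected with confidence

felsen_table(sc$tree, occ, sc$clades)
#>   clade variable    beta n_species
#> 1    R1      SPP 0.06775        16
#> 2    R1     CTRL 0.00303        16
```

The clade diversified at `r₀ ≈ 0.21` speciation events/MY; γ = −1.21 hints
at a slowdown but neither the MCCR test (p = 0.11) nor ΔAIC_RC = 1.06
rejects rate constancy — as expected for a constant-rate simulation. SPP
preferences evolved ~20× faster than the control's (0.068 vs 0.003
felsens). The spatial decomposition and overlap stages complete the triad:

```r
signal_decomposition(sc$tree, occ, sc$clades)[, c("variable", "phi")]
#>   variable phi     # SPP fully spatially structured, CTRL not
#> 1      SPP   1
#> 2     CTRL   0

clade_overlap_summary(occ, sc$clades, sc$grid, reps = 1000, seed = 43)$clade_summary
#>   clade variable mean_D prop_rejected n_pairs
#> 1    R1     CTRL  0.693         0.708     120
#> 2    R1      SPP  0.248         1.000     120
```

Species overlap far less on the gradient variable (mean D 0.25 vs 0.69) and
every SPP pair is ecologically distinct by the equivalency test — the
signature of a radiation driven by ecological differentiation along a
spatially structured gradient.

`run_pipeline(config, out_dir)` chains all stages (from files or from the
generator), writing per-stage CSVs plus a JSON manifest; reruns with the
same config are bit-identical.

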