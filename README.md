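# noisetissue

Quantifying stochastic gene expression in intact plant tissues from
nucleus-level fluorescence measurements.

Gene expression is noisy: even genetically identical cells in the same
tissue express a constitutive reporter at visibly different levels. With
two spectrally distinct reporters driven by identical promoters in the
same cell (a dual-reporter assay), that variability separates into an
**intrinsic** part — gene-copy-local fluctuations that decorrelate the two
reporters — and an **extrinsic** part — cell-global state (ribosomes,
polymerases, physiology) that moves both reporters together. A
**photoconvertible** reporter (green irreversibly switched to red by a
405 nm pulse) adds the time axis: after conversion, newly made green
protein reports synthesis while the red pool decays, so correlations
between read-outs 3 h and 6 h after the pulse measure how long expression
states persist. `noisetissue` implements the models and estimators for
this programme:

* an exact (Gillespie) simulator of the two-stage expression model
  `∅ → mRNA → protein` with first-order decay of both species, a
  green-to-red conversion event, and cell-to-cell variation of the
  translation rate ν₁ (gamma-distributed, quasi-static) as extrinsic
  noise — plus a matrix-exponential moment oracle and the closed-form
  non-stationary birth–death autocorrelation
  `c₀(t₂,t₁) = exp(−d(t₂−t₁)) · sqrt((1−e^{−d t₁})/(1−e^{−d t₂}))`
  that lower-bounds the two-stage model;
* the measurement pipeline for nucleus tables: duplicate averaging,
  per-image background subtraction and mean normalization,
  Kolmogorov–Smirnov channel-skew filtering, temporal correlations;
* the dual-reporter noise decomposition
  `η²_int = ⟨(c−y)²⟩ / (2⟨c⟩⟨y⟩)`,
  `η²_ext = (⟨cy⟩ − ⟨c⟩⟨y⟩) / (⟨c⟩⟨y⟩)` (reported ×100), with
  Wilcoxon rank-sum group comparisons and nuclear-area (ploidy-proxy)
  quartile analysis;
* a covariance-normalized estimator of the spatial coupling of extrinsic
  noise between neighbouring cells — cross-reporter covariance to the 39
  nearest neighbours, normalized by the within-cell cross-channel
  covariance — with a randomization test and five distance tiers;
* a cell-division inheritance simulation (mRNA/protein content copied to
  both daughters; translation rates redrawn or inherited) quantifying how
  much neighbour coupling inheritance alone explains;
* a synthetic-tissue generator with exact analytic ground truth, so every
  estimator is validated end-to-end without any external data.

Everything is data-frame-first and pipe-friendly: tables in, tibbles out,
with `tidy()`, `glance()` and `autoplot()` methods on result objects, and
a thin CLI (`inst/cli/noisetissue`) over the same functions.

## Worked example

```r
library(noisetissue)

# 1. Pulse-chase autocorrelation at the reference parameters
params <- kikgr_params()           # v0 = 2.25, d0 = 1.125, v1 = 45, d1 = 0.09 /h
autocorr_birth_death(params$d1, 3, 6)
#> [1] 0.5748673
autocorr_two_stage_mc(params, extrinsic_spec(45, 100), 3, 6,
                      n_traj = 1e4, seed = 1)
#> # A tibble: 1 × 5
#>      t1    t2     r   mc_se n_traj
#>   <dbl> <dbl> <dbl>   <dbl>  <dbl>
#> 1     3     6 0.760 0.00422  10000
```

The birth–death closed form (0.575) depends only on the protein decay
rate; the full model with extrinsic translation-rate noise (Var = 100 h⁻²)
lies above it at r ≈ 0.76 — persistent cell states slow the decay of the
autocorrelation.

```r
# 2. Synthetic dual-reporter tissue -> noise decomposition -> spatial coupling
gen  <- generate_tissue(tissue_gen_config(n_cells = 2000, coupling = 0.5,
                                          correlation_length_um = 25, seed = 8))
norm <- gen$table |> average_duplicates() |> normalize_table()
aggregate_noise(norm)
#> # A tibble: 1 × 6
#>   image_id      tissue     n_cells eta2_int eta2_ext eta2_tot
#>   <chr>         <chr>        <int>    <dbl>    <dbl>    <dbl>
#> 1 synthetic_img young_leaf    2000     16.7     31.7     48.4

sc <- spatial_coupling(norm, spatial_config(n_permutations = 5000, seed = 1))
glance(sc)
#> # A tibble: 1 × 7
#>       r  p_value n_cells mean_nn_distance_um ci_lower ci_upper n_permutations
#>   <dbl>    <dbl>   <int>               <dbl>    <dbl>    <dbl>          <int>
#> 1 0.265 0.000200    2000                12.9    0.208    0.330           5000
```

`eta2_int`/`eta2_ext` are the intrinsic and extrinsic squared noise
(×100); the generator's analytic targets for this configuration are 16.7
and 33.4. The coupling `r` is the fraction of the extrinsic-noise variance
shared with the nearest neighbour; `p` comes from jointly permuting the
(CFP, YFP) pairs across positions (the smallest attainable value here,
1/5001, indicates no permutation reached the observed coupling).

```r
# 3. How much coupling does division inheritance explain?
cfg <- inheritance_config(params, extrinsic_spec(45, 100),
                          mode = "state_only", n_pairs = 1e4, seed = 2)
sibling_correlation(simulate_division_pairs(cfg))
#> # A tibble: 1 × 6
#>   mode       n_pairs mean_division_age_h     r  mc_se normalization
#>   <chr>        <int>               <dbl> <dbl>  <dbl> <chr>
#> 1 state_only   10000                37.8 0.175 0.0162 covariance
```

Copying mRNA and protein content to both daughters while redrawing their
translation rates sustains a sibling coupling of ≈ 0.17 (prediction 0.16) at the calibrated
mean division age — inheritance of content alone explains only part of a
neighbour coupling in the 0.34–0.42 range (see the methods vignette for
the full-inheritance case and its estimator subtleties).

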