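# larimorph

Phylogenetic comparative analysis of wing morphology and wing pigmentation
in gulls (Larinae).

Gulls vary enormously in how dark their upperwings are — from the all-white
Ivory Gull to the near-black mantle of the Great Black-backed Gull — and
dark feather surfaces have been shown to reduce skin-friction drag in
gliding flight. `larimorph` implements the comparative pipeline for testing
whether **wing loading** (body mass per unit wing area, g·mm⁻², a proxy for
how hard a species must work to stay aloft) predicts **mantle darkness**
(Kodak grey scale, 0–19) and the **proportion of black on the wingtips**,
with **absolute latitude** (distance of the range centroid from the equator,
a proxy for insolation) as a covariate, while controlling for shared
ancestry. It is aimed at evolutionary ecologists and anyone who needs
reusable, tested building blocks for PGLS model comparison or beta
regression with a phylogenetic random effect.

## What it computes

**Morphometrics.** Wing area from hand length H, first secondary length S
and wingspan W as `(W − 2H)·S + 2(H·S/2) = S·(W − H)`; wing loading
`mass / area`; aspect ratio `W² / area`; z-scored wing loading (population
SD) and absolute latitude.

**Mantle darkness (PGLS).** The regression
`KGS ~ β₀ + β_WL · WL_std + β_AL · |lat|` is fitted by maximum likelihood
under four residual-covariance models:

- **NP** — non-phylogenetic, `V = σ² I`;
- **BM** — Brownian motion, `V_ij = σ² t_ij` with `t_ij` the shared
  root-to-MRCA branch length;
- **OU** — Ornstein–Uhlenbeck with selection strength α (fixed-root form),
  `V_ij = σ²/(2α) · e^(−α d_ij) (1 − e^(−2α t_ij))`;
- **LAMBDA** — Pagel's λ, off-diagonal entries of the BM matrix scaled by
  λ ∈ [0, 1], with a profile 95% CI.

The extra-parameter models (OU, λ) are compared against NP and BM by
likelihood-ratio tests, and the OU phylogenetic half-life is `ln 2 / α`.

**Wingtip black (phylogenetic beta regression).** Proportions are squeezed
off the boundary (0 → 10⁻⁴, 1 → 0.9999) and modelled as
`y_i ~ Beta(μ_i φ, (1 − μ_i) φ)` with
`logit(μ_i) = x_iᵀβ + u_i`, `u ~ MVN(0, σ²_p C)` where `C` is the
phylogenetic correlation matrix. The marginal likelihood is maximized by a
Laplace approximation; exponentiated coefficients are ratios analogous to
odds ratios, and simulated quantile residuals check calibration.

**Ancestral states, OLS, adequacy.** Joint-ML ancestral mantle states under
BM (with along-branch interpolation for gradient tree plots); OLS of aspect
ratio on standardized wing loading; and a simulate-and-refit adequacy check
that asks whether OU-over-BM selection could be a tree artifact by refitting
both models to traits simulated under each fitted model and comparing
ΔAIC distributions with the observed value.

A seeded synthetic-data generator (`simulate_tree()`,
`simulate_species_table()`) produces 50-species studies with the same
statistical structure, so the whole pipeline runs and is tested without any
external download.

## Worked example

```r
library(larimorph)

tree  <- simulate_tree(n_tips = 50, height = 0.21, seed = 7)
table <- simulate_species_table(tree, generator_config(seed = 7))
morph <- derive_morphology(table)
d     <- prepare_analysis(morph)   # complete cases, re-standardized WL

cmp <- pgls_compare(d, tree, mantle_kgs ~ wing_loading_std + abs_latitude)
cmp$table
#> # A tibble: 4 × 7
#>   model  param  sigma2 loglik   aic lrt_p_np  lrt_p_bm
#>   <chr>  <dbl>   <dbl>  <dbl> <dbl>    <dbl>     <dbl>
#> 1 OU      154. 2495.    -121.  252.  0.00571  5.05e-11
#> 2 LAMBDA    0    41.2   -125.  260.  1        2.53e- 9
#> 3 NP       NA     8.64  -125.  258. NA       NA
#> 4 BM       NA   359.    -143.  293. NA       NA

half_life(cmp$fits$OU)
#> [1] 0.004492413
```

On this synthetic draw the OU model wins the likelihood-ratio comparison
against both NP (p ≈ 0.006) and BM (p < 10⁻¹⁰), and its half-life
(~0.0045 tree units on a height-0.21 tree) says phylogenetic correlation in
mantle darkness decays quickly — the same qualitative regime as the real
gull data. The wingtip model reads the same way:

```r
dw  <- prepare_analysis(morph, c("wing_loading", "abs_latitude", "wingtip_black"))
fit <- fit_phylo_beta(dw, tree, wingtip_black ~ wing_loading_std + abs_latitude)
tidy(fit)
#> # A tibble: 3 × 6
#>   term             estimate std.error ratio statistic  p.value
#> 1 (Intercept)        1.13     0.299   3.10       3.79 1.49e- 4
#> 2 wing_loading_std   0.236    0.0678  1.27       3.48 5.05e- 4
#> 3 abs_latitude      -0.0501   0.00436 0.951    -11.5  1.75e-30

predict_proportion(fit, wl_std = c(0, 1, 2), abs_lat = 0)
#> [1] 0.7555038 0.7963960 0.8320253
```

Each `ratio` is `exp(estimate)`: here a one-SD increase in wing loading
multiplies the predicted black:non-black ratio on the wingtip by ~1.27, and
each degree of latitude shrinks it by ~5%. `run_pipeline(pipeline_config())`
chains every stage (fits, ancestral states, adequacy check) and writes
CSV/JSON reports; `inst/cli/larimorph.R` is a thin shell wrapper around the
same functions.

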