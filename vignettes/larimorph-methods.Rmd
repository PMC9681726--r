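---
title: "Models and methods behind larimorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind larimorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`larimorph` packages a comparative analysis of gull (Larinae) wing
morphology and pigmentation. This vignette explains the models it fits, the
assumptions behind them, the numerical choices made where several were
defensible, and what the synthetic-data generator does and does not emulate.

## Morphometric derivations

Wing area is approximated from three field measurements — wingspan $W$,
hand length $H$ (the standard "wing length") and first secondary feather
length $S$, all in mm — as a central rectangle plus two triangular hand
sections:

$$\text{area} = (W - 2H)\,S + 2\!\left(\tfrac{1}{2} H S\right) = S\,(W - H).$$

The algebraic identity on the right is used as a machine-precision test
invariant. Wing loading is **mass / area** (g·mm⁻²). The conventional
definition, the printed units and the plausible range for gulls
(roughly 0.002–0.007 g·mm⁻² for 90–2000 g birds) all require mass in the
numerator, so that orientation is fixed here even though it is easy to
state backwards. Aspect ratio is $W^2/\text{area}$, unitless.

Wingspans reported as ranges enter as their midpoint. Subspecies rows are
averaged up to species with pairwise exclusion of missing values.
Standardized wing loading is a z-score using the **population** SD
(divisor $n$); with the sample convention every coefficient "per SD"
changes by $\sqrt{n/(n-1)}$, about 1% at $n = 50$, which is documented
rather than hidden. Missing data are handled complete-case per analysis,
and the z-score is recomputed on each analysis's complete set
(`prepare_analysis()`), so "mean wing loading" always means the analysed
sample's mean.

## The four mantle-darkness models

Mantle darkness (Kodak grey scale, 0 = white to 19 = black) is regressed on
standardized wing loading and absolute latitude. The four models differ
only in the residual covariance $\sigma^2 C_0$:

| model | $C_0$ | extra parameter |
|---|---|---|
| NP | $I$ | — |
| BM | $t_{ij}$ (shared root-to-MRCA branch length) | — |
| OU | $\frac{1}{2\alpha} e^{-\alpha d_{ij}}\left(1 - e^{-2\alpha t_{ij}}\right)$ | $\alpha$ |
| LAMBDA | $t_{ij}$ with off-diagonals $\times\,\lambda$ | $\lambda$ |

with $d_{ij}$ the patristic distance. The OU form is the **fixed-root**
variant (trait starts at the root optimum); several variants circulate and
the choice is stated here so it can be audited. Latitude enters
unstandardized — its coefficient is "per degree from the equator" — while
wing loading enters z-scored.

Everything is **ML, never REML**: the point of the exercise is
likelihood-ratio comparison across models, and REML likelihoods are not
comparable when the covariance family changes. Reported coefficient
standard errors use the $n-p$ residual denominator with $t_{n-p}$ p-values,
the usual GLS reporting convention. AIC counts $k = p + 1$ parameters for
NP/BM (coefficients plus $\sigma^2$) and one more when $\alpha$ or
$\lambda$ is estimated.

### Profiling the covariance parameter

For fixed $\alpha$ or $\lambda$, $\hat\beta$ and $\hat\sigma^2$ have closed
forms, so only a one-dimensional concentrated likelihood needs numerical
work. $\alpha$ is profiled on the log scale over
$[10^{-8}/h,\ 10^{3}/h]$ ($h$ = tree height): a 50-point log-spaced grid
scan locates the basin and `stats::optimize` refines it at tolerance
$10^{-8}$, with the result checked against the grid maximum. A grid scan
plus local refinement was preferred over a small number of multistarts
because the concentrated OU likelihood can be multimodal on short trees and
the grid is cheap ($O(n^3)$ per point at $n = 50$). The lower bound is set
deep enough that the Brownian model is numerically attainable at the
boundary ($\alpha h = 10^{-8}$ reproduces the BM log-likelihood to well
under $10^{-6}$), which is also what makes the adequacy harness's
per-replicate invariant $\ell_{OU} \ge \ell_{BM}$ hold. $\lambda$ is
profiled over $[0, 1]$ with both endpoints evaluated explicitly; a maximum
at an endpoint is flagged as a boundary fit.

Likelihood-ratio tests use the plain $\chi^2_1$ tail even when the MLE sits
at a boundary ($\lambda \in \{0, 1\}$, $\alpha$ at its floor). The boundary
mixture correction is deliberately omitted — matching common practice in
this literature — which makes the test conservative for a null on the
boundary; a property test verifies the empirical size at $n = 50$ stays
within [0.02, 0.09] at nominal 0.05. The $\lambda$ 95% CI is the profile
interval where the log-likelihood is within $\chi^2_{1,0.95}/2 = 1.92$ of
its maximum, clipped to $[0, 1]$; a profile flat to within that drop
returns the full interval with a warning. The OU phylogenetic half-life is
$\ln 2 / \hat\alpha$, the time for the expected trait to move halfway to
the optimum.

Matrix solves go through Cholesky factorization and fail loudly (naming the
offending structure) rather than jittering the matrix: a non-PD covariance
here always indicates a malformed tree or parameter, not noise. An exactly
interpolating fit (residual quadratic form numerically zero) is flagged
`degenerate` instead of reporting an unbounded likelihood.

## Phylogenetic beta regression for wingtip black

The proportion of black on the wingtip is bounded, so it is modelled as
Beta-distributed with a logit link and a phylogenetic random effect:

$$y_i \sim \mathrm{Beta}(\mu_i \phi,\ (1-\mu_i)\phi), \qquad
\operatorname{logit}(\mu_i) = x_i^\top \beta + u_i, \qquad
u \sim \mathrm{MVN}(0,\ \sigma^2_p C),$$

where $\phi > 0$ is the precision and $C$ is the MRCA-depth matrix divided
by tree height — a **unit-diagonal correlation matrix**, so $\sigma^2_p$ is
a variance on the logit scale. (The covariance scaling is a genuine free
choice; normalizing to a correlation matrix is the common random-effect
convention and makes $\sigma^2_p$ interpretable.) Exact 0s and 1s, which
occur in real wingtip scoring, are squeezed to $10^{-4}$ and $0.9999$
before fitting; with only a handful of boundary species a zero-one-inflated
model is not warranted.

The marginal likelihood integrates over $u$ by a **Laplace approximation**:
an inner Newton optimization finds the conditional mode $\hat u$ (Fisher
scoring steps with halving, so each step direction uses a guaranteed
positive-definite Hessian; the final determinant uses the observed Hessian
when it is PD), and an outer Nelder–Mead over
$(\beta, \log\phi, \log\sigma^2_p)$ is polished with BFGS using tightened
numeric-gradient steps, because the simplex reliably stops
$\sim 10^{-4}$ short on these flat surfaces. At $\sigma^2_p = 0$ the code
takes the exact plain-beta branch, so the Laplace likelihood equals the
plain beta-regression likelihood with no approximation error — a tested
identity, and the route by which the fit is validated against an
independent numeric ML oracle. Coefficient inference is Wald ($z$), and
$\hat\sigma^2_p$ drifting below $10^{-6}$ is flagged as a boundary fit.

Exponentiated coefficients are ratios of black to non-black area, analogous
to odds ratios; `predict_proportion()` inverts the logit at the
population level (random effect at 0). Model calibration is checked with
simulated quantile residuals: each observation's quantile among draws from
its fitted predictive distribution (random effect re-sampled), uniform
under a correct model, summarized by a KS p-value. The default 250
predictive draws make the residual quantiles stable to about $\pm 0.03$.

## Ancestral states

Ancestral mantle states use the **joint ML** criterion under BM: internal
states minimize $\sum_{\text{edges}} (\Delta\text{state})^2/\text{length}$,
a sparse quadratic problem solved exactly via the graph Laplacian
partitioned on tips versus internal nodes. Joint ML was chosen over
interpolating marginal estimates because it has a clean optimality contract
that can be verified against brute-force minimization, and for a Gaussian
model the joint mode coincides with the posterior mean given the tips. Two
consequences are tested as invariants: reconstructed states always lie
within the tip range (maximum principle), and the reconstruction is
equivariant under affine transformations of the trait. Zero-length edges
are rejected with an error — silently jittering a published tree is the
caller's decision, not the package's. Branch gradients for plotting
interpolate linearly along each edge, 20 segments per edge by default.

Pruning a tree to the analysis species keeps any collapsed basal path as a
root edge, so root-to-MRCA depths keep referring to the original root and
pruning commutes exactly with subsetting the covariance matrix.

## The adequacy check

Selecting OU over BM on a short, shallow tree can in principle be an
artifact of the tree shape. The harness refits both models to traits
simulated under **each fitted model** (exact MVN draws using the fitted
$\hat\beta$, $\hat\sigma^2$, $\hat\alpha$ — the natural reading of
"simulate from the model", since defaults would test a different
hypothesis) and records $\Delta\mathrm{AIC} = \mathrm{AIC}_{BM} -
\mathrm{AIC}_{OU}$ per replicate. The observed $\Delta$AIC's quantile
within each simulated distribution is reported as a calibrated descriptive
comparison; no formal p-value is constructed because the published
comparison is itself informal. 500 replicates is the reference setting;
tests run 100 for speed. All randomness flows from one seed and results are
bit-for-bit reproducible.

## What the synthetic generator does and does not emulate

`simulate_tree()` draws a pure-birth tree rescaled to height 0.21 tree
units — the height of the dated gull tree, treated as opaque time units and
never rescaled. `simulate_species_table()` then builds a measurement table
whose *derived* quantities land where real gulls land: masses log-uniform
on [90, 2000] g; wingspans allometric ($\propto$ mass$^{1/3}$, ±3%
truncated log-normal noise, clipped to [550, 1800] mm); hand length
0.32–0.40 of wingspan and secondary length 0.38–0.50 of hand length, chosen
so wing loading falls in ≈[0.002, 0.007] g·mm⁻² (hard envelope
[0.001, 0.010] across 100 seeded draws, a tested generator contract) and
aspect ratio in ≈8–12. Mantle darkness is drawn from the OU regression with
coefficients (10.38, 1.22, −0.07), $\alpha = 27.13$ and
$\sigma^2 = 595.77$ — so the stationary SD
$\sqrt{\sigma^2/2\alpha} \approx 3.3$ KGS keeps draws mostly inside the
0–19 scale (clipping is logged) — and wingtip proportions from the
phylogenetic logit-beta model with coefficients (1.65, 0.34, −0.05),
$\phi = 30$, $\sigma^2_p = 0.5$, rounded at $10^{-4}$ so exact 0s and 1s
arise through the observation process as they do in real scoring. Latitudes
are uniform on [−70, 70]° and independent of the tree, mirroring how the
analysis treats latitude as a fixed covariate. Trait simulation is an exact
Cholesky MVN draw on the tree, not an Euler walk — identical distribution,
simpler contract.

What this generator does **not** emulate: real gull taxonomy and tree
shape (a birth-death MCC tree with its particular imbalance), measurement
error in field wingspans, correlation between latitude and body size, or
the full column schema of trait databases. Passing tests therefore
demonstrate that the estimators recover the structure they assume, at the
study's sample sizes, on trees of the study's scale — not that the
published coefficient values are reproduced, which requires the archived
data deposit and dated tree. Those files are accepted as optional inputs
(`pipeline_config(species_csv =, tree_file =)`) via exact species-name
matching after underscore/space normalization.

## Problem sizes and defaults

Defaults mirror the study conditions: 50 species (49 in the wingtip
analysis), tree height 0.21, 500 adequacy replicates. The test suite
exercises the same code at reduced but still informative sizes — 200
replicates for parameter-recovery coverage, 100 for the adequacy harness
and residual-calibration checks — with every stochastic case seeded.
Coverage checks target the wing-loading coefficient, the effect of
scientific interest. Known limitations: a single scalar covariance
parameter per model (no multi-optimum OU, no measurement-error model), Wald
rather than profile inference for the beta regression, plain $\chi^2$
boundary behaviour for the LRTs, and no uncertainty intervals on ancestral
states.
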