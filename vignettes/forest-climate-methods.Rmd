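---
title: "Methods: window-paired forest-climate analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-paired forest-climate analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestclim)
```

This vignette documents the statistical machinery in `forestclim`: the models,
their assumptions, the tunable parameters and their defaults, the numerical
choices, what the synthetic generator does and does not emulate, and the known
limitations.

## The estimation problem

A change in forest cover inside a ~5 km cell perturbs the surface energy
balance through two mediators with opposite signs: albedo (less forest →
brighter surface → cooling) and evapotranspiration (less forest → less
latent-heat flux → warming). The local LST response is confounded by the
regional climate trend every cell experienced over the same decade. The
package's answer to the confounding is *pairing*: within each small search
window, the change in a strongly changed (focal) cell is contrasted with the
change in an essentially unchanged (reference) cell a few kilometres away.
Any background signal smooth at scales much larger than a window cancels in
the contrast, up to `max|∇g| × window diagonal` — a bound the test suite
checks explicitly.

## Grid conventions and preparation

All layers live on one regular lat/lon grid (default 0.05°), row-major from
the northwest corner, with coordinates at cell centers. Fine cover maps are
block-averaged (`upscale_mean`, masked cells excluded, empty blocks masked);
coarser products are brought over by bilinear interpolation
(`resample_bilinear`). A target cell adjacent to any masked source cell is
masked rather than filled — the conservative choice when the upstream product
gives no guidance. Quality rules mask, never alter: LST needs emissivity
error ≤ 0.02 and LST error ≤ 2 K; albedo accepts flags {0, 1, 2}; an ET cell
must be complete in all 36 fine subpixels. Temporal collapsing is always a
mean of means (day/night first, then months; 8-day composites to months,
then months to the year), which differs from a pooled mean when counts are
unequal. How to treat months with a missing day or night member is not
settled by the data products; the package defaults to any-valid with at
least one valid month per cell, with `require_all = TRUE` available.

Epochs: forest change uses cover(2010) − cover(2000)-style endpoint
differencing; climate changes are offset one year later (2011 − 2001) so
that the presumed cause precedes the consequence. Passing matching epochs
reproduces the same-epoch robustness variant.

## Window search

Windows are 5 × 3 cells (lon × lat) with stride 2 × 2 — the stride follows
from the stated overlap of 3 cells in longitude and 1 in latitude. Within a
window the focal cell maximizes |ΔF| among cells with |ΔF| > 15% and the
reference minimizes |ΔF| among cells with |ΔF| < 5% (both strict); if either
set is empty the window yields nothing. Deterministic choices the source
method leaves open, fixed here and exercised in tests: windows are scanned
row-major from the northwest; ties on |ΔF| go to the first cell in row-major
order; windows that do not fit entirely inside the grid are dropped (no
padding, no longitude wraparound); when two windows select the identical
(focal, reference) pair only the earliest occurrence is kept; a pair's region
(tropical ≤ 20°, temperate ≤ 50°, boreal beyond, boundaries equatorward) and
its deforestation/forestation category come from the focal cell. Pairs carry
each variable independently: a pair missing ΔLST at either member still
contributes its ΔET, so different analyses legitimately use different pair
counts.

## Paired mixed model and structure selection

For one variable, the focal-vs-reference test is a linear model on two
observations per window (reference change, focal change) with a cell-type
fixed effect, a window random intercept, and residual spatial correlation.
The package fits this by profiling: for given correlation parameters θ =
(range, variance ratio), the fixed effects and residual variance have closed
forms, and θ is optimized numerically on the log scale (objective tolerance
1e−10; a deterministic 25-point log-grid brackets the 1-D range search
because the profile can be multimodal; the 2-D case uses Nelder–Mead from
three deterministic starts). Five correlation families are available —
exponential, gaussian, rational quadratic, spherical, linear — all functions
of Euclidean distance in raw (lon, lat) degrees, matching the method's
stated `~ longitude + latitude` form; no great-circle correction and no
nugget. REML supplies reported coefficients and standard errors; ML supplies
the likelihoods compared across structures by
AICc = −2 logLik + 2k + 2k(k+1)/(n−k−1), where k counts fixed effects,
correlation/variance parameters and σ². Which likelihood the original
selection used is not stated; ML is the default here because it keeps
likelihoods comparable across identical fixed effects, and the choice is an
argument. Under the independence structure the paired model collapses
exactly to the paired t-test — estimate, t and p to numerical precision —
which is why the cell-type coefficient is referred to n_windows − 1 degrees
of freedom. Confidence intervals are estimate ± 1.96 SE; p-values use a t
reference with the residual degrees of freedom.

## Piecewise structural equation model

The causal diagram has ΔF exogenous and three recursive equations:
Δalbedo ~ ΔF; ΔET ~ ΔF + Δalbedo; ΔLST ~ ΔF + Δalbedo + ΔET. Each equation
is fitted by the same GLS engine on the pairs that carry all four variables,
anchored at focal-cell coordinates (which member anchors the pair is not
prescribed anywhere; the focal cell is the active one). Standardized
coefficients are raw × sd(x)/sd(y) with SDs taken from the analysis subset.
Links with p > 0.05 are flagged for display but retained in all arithmetic.
R² is 1 − RSS/TSS on raw residuals (the squared fitted–observed correlation
is also reported; GLS admits no single canonical R²).

Two numerical points deserve emphasis. First, *tied locations are
inadmissible* under nugget-free spatial correlation: if the window search
retains one focal cell paired with two different references, those rows have
zero distance and correlation exactly 1, and any jitter-based workaround
forces their residuals toward equality, which badly distorts the
coefficients (we observed order-of-magnitude inflation before adopting the
rule). `fit_path_model` therefore keeps only the earliest-window pair per
focal location, and `fit_gls` refuses exact duplicates with an informative
error. Second, a small diagonal jitter (starting at 1e−10, escalating, and
recorded in the fit) is still applied when the Cholesky factorization fails
at *distinct* coordinates — the gaussian family at long range is the usual
culprit — and the profile objective rejects parameter regions where the
whitened design's condition number collapses.

Pruned diagrams are tested by d-separation: for every non-adjacent ordered
pair, independence conditional on the union of both variables' parents,
tested by adding the claimed-independent variable to a GLS regression with
the same structure and reading its p-value; the basis is ordered
deterministically. Fisher's C = −2 Σ ln pᵢ is referred to χ² with 2k df. The
saturated diagram has an empty basis, so its global fit is untestable — only
the component fits (residuals, R²) speak for it.

The decomposition is exact arithmetic on the standardized link table: total
= direct + (ΔF→Δalbedo→ΔLST) + (ΔF→ΔET→ΔLST) + (ΔF→Δalbedo→ΔET→ΔLST), each
indirect term a product of standardized coefficients. For a linear recursive
system the total equals the population standardized simple-regression slope
of ΔLST on ΔF (path tracing), a convergence the tests verify at n = 5000.

## Scenario projection

`project_dlst` maps a scenario ΔF raster to predicted ΔLST per cell as
total × (ΔF / sd_ΔF) × sd_ΔLST. This equals full propagation through the
linear system, is exactly linear in ΔF, applies no clipping outside the
fitted ΔF range, and embeds a stationarity assumption — the fitted
relationships persist over the scenario horizon — that is carried in the
output object rather than silently. Coarser scenario rasters should be
brought to the analysis grid with `resample_bilinear` first. Summaries
(mean, min, max) enumerate valid cells only.

## The synthetic generator

`generate_landscape` emulates exactly the statistical structure the analysis
assumes: decadal forest change concentrated on clustered square patches of
side 1–3 cells (patch magnitudes uniform 15–100%, sign by the forestation
fraction, density set by `change_patch_rate`, default 0.05), near-zero
change (uniform ±5%) elsewhere; climate changes generated cell-by-cell from
the linear structural equations on the standardized scale; noise that is
part independent, part spatially correlated; a smooth regional background
trend added to every climate change field; epoch-1 levels as smooth fields
with epoch 2 = epoch 1 + change; and per-cell QC failures at rate 0.02.
`generate_pairs` draws the pair table directly (focal magnitudes from the
same mixture, both members sharing a window-level background) for fast
statistical tests.

Default structural coefficients (s_FA = −0.4, s_FE = 0.5, s_AE = −0.12,
s_FL = −0.23, s_AL = 0.2, s_EL = −0.6) give a standardized total effect of
−0.639 — the regime reported for Brazilian pair data — and are a convention,
not an estimate. Noise SDs default to the values that give every variable
unit population variance, so the implied population R² per equation
(`implied_moments`) is simply the explained variance, and the fitted R²
must match it within sampling error — a bookkeeping identity the tests
check at n = 2500. The spatially correlated noise component defaults to a
0.1° correlation length, deliberately *below* the window scale: noise
correlated across a whole window would partially cancel in the
focal-reference contrast and silently shrink the endogenous SDs, biasing
standardized coefficients upward (we measured ~0.08 inflation at a 0.5°
length). Regional-scale structure is instead represented by the explicit
background trend (default amplitude 2 standardized units, 10° wavelength ≈
40 window widths), whose contribution to paired contrasts the tests bound
below 2% of variance. What the generator does **not** emulate: sensor noise
and cloud-gap geometry, realistic biome boundaries, seasonal dynamics, and
any nonlinearity — so passing tests demonstrate correctness of the
machinery under the model's own assumptions, not fidelity to any particular
satellite product.

Problem sizes used by the checks were chosen to estimate each quantity
stably: 200 random grids for the pairing oracle, 2000–5000 pairs for
coefficient recovery, 300 replicates at n = 300 for CI coverage, 100
simulations at n = 500 per regime for structure selection, 1000 simulations
for the Fisher's C type-I rate, and a 160 × 160-cell landscape
(~1500 complete pairs) for the end-to-end run.

## Known limitations

- Euclidean degrees distort longitudinal distance at high latitude; this is
  faithful to the stated method, not a recommendation.
- Dense-matrix likelihoods scale as O(n³); beyond a few thousand
  observations per fit, subset or block the data.
- No nugget means measurement error loads onto the range estimate, and tied
  locations must be thinned (see above).
- The region classification at exactly 20°/50° is assigned equatorward; both
  thresholds are arguments.
- The projection inherits every caveat of the fitted model, most visibly
  stationarity and linearity in ΔF.
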