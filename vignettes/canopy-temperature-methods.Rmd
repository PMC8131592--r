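---
title: "Methods: sub-pixel canopy temperature estimation and attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sub-pixel canopy temperature estimation and attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, the numerical
choices, and what the synthetic scenes do and do not establish about real
data.

## The mixing model and its assumptions

A thermal pixel at ~70 m aggregates radiance from every surface element it
contains. Writing `fₖ` for the areal fraction of class `k` in the pixel,
`εₖ` for a class emissivity, and working in fourth-power (radiance)
temperature space, the pixel-level balance is

    ε(i,j) · LST(i,j)⁴ = Σₖ εₖ · fₖ(i,j) · Tₖ⁴ + r(i,j),

with residual `r`. The central assumption is **local thermal uniformity**:
within a small neighborhood (5×5 pixels, 350 m), each class has a single
temperature `Tₖ`. That buys linearity — the 25 pixel equations of a window
share 8 unknowns `xₖ = Tₖ⁴` — at the cost of biasing estimates wherever the
assumption fails (park edges, shorelines, strong within-window gradients).
The window size trades identifiability (more equations, better
conditioning) against validity of the uniformity assumption;
`kernel_sensitivity()` quantifies this on scenes with known truth, and the
package default is 5.

Two secondary simplifications:

* **Class-constant emissivity.** One `εₖ` per class (configurable table),
  rather than per-pixel class emissivities, which no standard product
  supplies. Pixel emissivity for composition is the fraction-weighted mean
  `Σ fₖ εₖ`, which makes the forward model and the unmixing model
  mutually consistent at zero residual.
* **Observation noise in Kelvin.** Sensor noise is specified as a
  temperature (default 0.5 K), added to composed LST, not to radiance.

## The bounded solve

Each window solve is `min ‖Ax − y‖²` with `A[p,k] = εₖ fₖ(p)`,
`y[p] = ε(p)·LST(p)⁴`, subject to box bounds `t_min⁴ ≤ xₖ ≤ t_max⁴`. The
bounds default to the minimum and maximum land-pixel LST of the image —
element temperatures are not expected outside the range the image itself
exhibits — and act as the outlier suppressor for poorly identified
classes. The solver is a Stark–Parker bounded-variable active-set
iteration with a fast path (accept the unconstrained solution when it is
interior). Numerical choices:

* Variables are scaled by `t_max⁴` before solving, so tolerances
  (`1e-10` on the scaled KKT conditions) are unit-free.
* Classes **absent** from a window (zero fraction) are excluded; classes
  **present but rare** (window-mean fraction below `min_fraction`, default
  0.02) stay in the design — removing their radiance would bias every
  other class — but their own estimates are reported as NaN, since they
  are not identifiable.
* If the design is numerically rank deficient, the class with the
  smallest summed fraction is dropped repeatedly (a deterministic
  tie-break) and the window is flagged `rank_deficient`. Flagged windows
  are reported but carry no exactness guarantee: collinear classes share
  their radiance, so individual temperatures are blends. In noise-free
  validation scenes these windows are the only source of recovery error,
  which is why recovery checks condition on the `ok` flag (and assert
  that flagged windows stay a small minority).
* Windows with fewer than 8 usable pixels are not solved.

When a true temperature lies outside the bounds, the estimate sits exactly
on the bound and the unmet radiance spills into the free classes — the
intended behavior of the constraint rule, tested explicitly.

## Anomalies and diurnal summaries

Per overpass, the canopy map (tree-class temperature where the pixel's
tree fraction is at least `canopy_fraction_min = 0.05`) is referenced to
the **land-only** domain-mean LST of the original image (water pixels
excluded so waterbody thermal inertia does not shift the reference; the
sensor image is used, not the decomposition, so the reference is
independent of solver behavior). Because the reference is a scalar, the
spatial STD of the anomaly is identical to the STD of the canopy map — a
useful invariance when comparing maps whose reference convention is
unknown. Summary statistics use the population STD (a map-wide descriptive
statistic); day/night labels come from per-overpass sunrise/sunset
metadata.

## Covariates

* **GAF**: tree + grass fraction, block means at the analysis scale.
* **DTW**: connected water components (8-connectivity, so diagonal
  channels are continuous) with area ≤ 500 m² are discarded; distances
  are exact center-to-center Euclidean (two-pass parabolic-envelope
  transform, verified against brute force), reported in km, evaluated at
  block centers.
* **BH**: area-weighted mean building height, dividing by the **built**
  area of the block — "the mean height of the buildings present" — with
  the divide-by-total-area convention available as an option. Blocks
  without buildings get 0.

## The attribution GAM

At the 350-m neighborhood scale (5×5 pixel blocks; anomaly and covariates
aggregated as above) the model is

    ΔLST ~ s(GAF, k=6) + s(DTW, k=6) + s(BH, k=3)
           + ti(GAF, DTW, k=c(4,4)) + ti(DTW, BH, k=c(4,3))
           + s(x, y, k=10)

fitted with `mgcv` by REML, one fit per overpass (no smoothing across
times of day). Basis dimensions are deliberately small so the fitted
curves describe large-scale trends rather than local texture; the spatial
smooth absorbs broad residual geography without competing with the
covariates. Choices worth recording:

* The interaction bases (4×4 and 4×3) are set below the main-effect
  bases, in the same restricted spirit; they are not separately tuned.
* At zone (borough-analogue) scale the spatial smooth is `s(x, y, k=3)`,
  which `mgcv` raises to its thin-plate minimum of 4 — the smallest
  admissible, nearly planar surface.
* Covariates that are constant in a zone, or undefined (DTW is +Inf when
  no waterbody qualifies), are dropped from the formula with a warning,
  and their MTE is 0 by definition.
* REML is the smoothing criterion; any penalized criterion would serve,
  but one had to be fixed for reproducibility.

**MTE** (maximum temperature effect) of a covariate is max − min of the
model prediction over a grid of that covariate, holding the other
covariates at their training medians and the spatial term at the domain
centroid; interaction terms therefore contribute at the conditioning
values. The conditioning is a choice — partial effects could equally be
read from `type = "terms"` — made so the MTE is a statement about
predicted ΔLST. Evaluation ranges matter: spline predictions in sparse
covariate tails (e.g. the top few percent of building heights) are
extrapolation-like and wiggly, so effect directions and MTEs should be
read over well-supported ranges; the recovery checks use the 95th
percentile of BH as the upper limit, mirroring the practice of choosing
per-region height ranges. `effect_share()` expresses MTEs as percentages
of their sum; this is one interpretation of a relative-importance
decomposition (effect ranges, not variance explained) and is labelled as
such.

## The synthetic scene generator

`generate_scene()` emulates the inputs of a coastal summer city:

* A fine categorical grid (default 10× the thermal resolution) built from
  thresholded smoothed Gaussian fields: contiguous parks, water
  concentrated along one edge (plus inland ponds) so shoreline distances
  span the domain, built blocks split into building/road/impervious/rail.
  Vegetation is split into tree/grass/bare by a field independent of
  total greenness — lawns and parks are distinct landscape elements — and
  15% of tree cover is scattered through the built fabric as street/yard
  trees. Both features are characteristic of real cities and give the
  class fractions the within-window variability that makes per-element
  solves identifiable.
* Class shares default to roughly a dense coastal city: 22% tree, 7%
  grass, 3% bare, 10% water, 25% building, 18% road, 12% other
  impervious, 3% rail.
* Element truth per overpass: class-specific diurnal harmonics (man-made
  surfaces warmest at midday; roads warmest among them at night; water
  nearly flat), plus injected effects on the canopy field — daytime
  `gaf_slope·GAF` (default −4 K), shoreline `dtw_amplitude·exp(−d/L)`
  (default −2 K, L = 0.5 km), building shadow `bh_day_coeff·log(1+BH)`
  (default −0.45 K) modulated by a solar half-sine peaking at mid-day;
  nocturnal `bh_night_coeff·log(1+BH)` warming (default +0.35 K, the
  sign-flipped sky-view-factor effect) — plus spatially correlated
  micro-variability (0.3 K) on every class.
* Observation: the exact forward radiance composition plus 0.5 K Gaussian
  noise (a plausible figure for a spaceborne thermal retrieval; the
  sensitivity to this choice is covered by the noise-monotonicity test).

**What passing tests show, and what they do not.** The scenes satisfy the
mixing model by construction (aside from injected violations of window
uniformity), have exactly known fractions, and carry additive Gaussian
noise. Real imagery adds fraction errors from land-cover misclassification
and geolocation, emissivity errors, atmospheric residuals, view-angle
effects, and cloud contamination — none of which are simulated. Passing
recovery tests therefore validates the estimator under its own
assumptions; it does not bound errors on real scenes.

Validation protocols fix the truth to be constant on 5×5 tiles and score
recovery at tile centers, where the solve window coincides with a tile and
the uniformity assumption holds exactly; off-center scores mix solver
error with deliberate assumption violation and are used only for
comparative statements (e.g. kernel sensitivity). Exactness checks pass
wide explicit bounds (273–333 K) so that no true temperature sits on a
bound; operational runs use the per-image default rule.

Problem sizes used by the test suite and acceptance script — 250×250
pixels for the exactness check, 80×80 with 10 noise draws for noise
robustness, 160×160 (≥1000 neighborhoods) with 5 seeds for GAM recovery —
were chosen to make Monte-Carlo variability small relative to the margins
being tested.

## Known limitations

* Flagged (rank-deficient) windows report blended temperatures; users
  should treat `condition` flags as a mask for quantitative work.
* The uniformity assumption biases estimates at sharp thermal boundaries;
  the anomaly reference partly absorbs the citywide component but not the
  local one.
* MTE shares are effect-range ratios, not a variance decomposition; they
  do not account for covariate correlation.
* The generator's diurnal base temperatures are stylized harmonics; the
  pipeline's diurnal statistics on synthetic scenes describe the
  generator, not any particular city.
* No CRS handling or reprojection: all layers are assumed co-registered
  north-up grids.
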