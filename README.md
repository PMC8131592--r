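# canotherm

Sub-pixel canopy temperature mapping and urban thermal attribution in R.

## What this solves

Moderate-resolution thermal sensors (~70 m) cannot resolve individual urban
surface elements: a single pixel mixes tree crowns, roofs, roads and water,
so the temperature of the tree canopy itself — the quantity that matters for
urban-forest heat stress — is not directly observable. `canotherm`
implements a downscaling pipeline for analysts of urban thermal imagery:

1. **Unmixing.** Assuming each of eight surface classes (tree canopy,
   grass/shrub, bare earth, water, building, road, other impervious,
   railroad) has a locally uniform temperature, pixel radiance obeys

   ```
   ε(i,j) · LST(i,j)⁴ = Σₖ εₖ fₖ(i,j) · Tₖ⁴ + r(i,j)
   ```

   where `fₖ` are areal class fractions and `εₖ` class emissivities. A
   5×5 moving window turns this into a bounded linear least-squares
   problem in `xₖ = Tₖ⁴`,

   ```
   min ‖A x − y‖²   subject to  t_min⁴ ≤ xₖ ≤ t_max⁴,
   ```

   with the bounds taken from the image's own land-pixel temperature range
   (an outlier-suppressing constraint rule), solved per window by an
   active-set bounded-variable algorithm and assigned to the window
   center.
2. **Anomalies.** Canopy maps are referenced to the land-only domain mean
   LST, `ΔLST = T_canopy − mean(LST_land)`, making overpasses from
   different days comparable.
3. **Diurnal summaries.** Spatial mean/STD of ΔLST per overpass, canopy
   vs element temperature contrasts, zonal means.
4. **Attribution.** A penalized-spline GAM at the 350-m neighborhood
   scale, `ΔLST ~ s(GAF, k=6) + s(DTW, k=6) + s(BH, k=3) + ti(GAF,DTW) +
   ti(DTW,BH) + s(x,y)` (REML), quantifies the effects of green-area
   fraction, distance to bluespace, and area-weighted building height;
   each covariate's **maximum temperature effect (MTE)** is the range of
   its predicted effect over a stated covariate interval.

A synthetic-scene generator produces full urban scenes (fine-grid land
cover, building heights, coastal water, injected GAF/DTW/BH effects with
known coefficients, observation noise) so every stage is testable against
ground truth without any data download. Covariate derivation (fraction
aggregation, area-weighted building height, exact Euclidean distance to
waterbodies > 500 m²) and plain-text georeferenced raster I/O are included.

## Worked example

```r
library(canotherm)

cfg <- scene_config(grid_rows = 60, grid_cols = 60, seed = 7)
sc  <- generate_scene(cfg)                  # land cover, BH, water, DTW
ov  <- scene_overpass(sc, hour = 13.0)      # truth + noisy LST at 13:00

st  <- decompose_image(ov$lst, sc$fractions, cfg$class_emissivities)
st
#> <element_stack> 60 x 60 pixels, kernel 5, bounds [294.5, 306.8] K
#>   solved pixel-classes: 12863; flagged windows: 79

canopy <- canopy_map(st, sc$fractions)           # tree fraction >= 0.05
delta  <- anomaly_map(canopy, domain_mean(ov$lst, !sc$water_mask), time = 13)
delta
#> <anomaly_raster> 60 x 60, ref 302.69 K, local time 13
#>   delta mean -4.47 K, sd 2.77 K over 2528 canopy pixels

tab <- build_neighborhood_table(delta, sc$gaf, sc$dtw, sc$bh, sc$zone_id)
fit <- fit_attribution(tab, scale = "city")
compute_mte(fit, "gaf", range = c(0, 1))$mte
#> [1] 3.720202
```

The anomaly mean of −4.5 K says canopy pixels at this (day) overpass sit
well below the city's land-mean surface temperature (the generator injects
greenspace, shoreline and building-shadow cooling on the canopy); the GAF
MTE of ≈3.7 K recovers the injected greenspace cooling of 4 K per unit
green fraction at solar noon to within the GAM's smoothing bias.

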