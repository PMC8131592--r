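Package: canotherm
Title: Sub-Pixel Canopy Temperature Mapping and Urban Thermal Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes moderate-resolution thermal imagery into per-element
    surface temperatures (tree canopy, grass, roads, roofs, and other urban
    surfaces) with a moving-window bounded least-squares unmixing of
    emissivity-weighted fourth-power radiance, forms spatial anomalies of
    canopy temperature against the land-only domain mean, summarizes diurnal
    patterns, and attributes spatial variation to greenspace coverage,
    distance to bluespaces and building height with generalized additive
    models. Ships a synthetic urban scene generator with known ground truth
    so the whole pipeline is testable end to end, plus covariate derivation
    (fractional land cover aggregation, area-weighted building height, exact
    Euclidean distance to qualifying waterbodies) and plain-text raster I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
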