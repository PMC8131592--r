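#' Synthetic scene configuration
#'
#' Parameters controlling the synthetic urban scene generator: grid size,
#' sub-pixel resolution, class emissivities, the diurnal sampling, and the
#' environmental effects injected into the canopy truth field. The defaults
#' emulate a coastal summer city observed every two hours at ~70 m: a
#' daytime greenspace cooling of 4 K per unit green fraction, an
#' exponential shoreline cooling of 2 K amplitude with a 0.5 km e-folding
#' length, building-shadow daytime cooling and reduced nocturnal cooling
#' (sign-flipped night warming), and 0.5 K observation noise.
#'
#' @param grid_rows,grid_cols coarse (thermal) grid size in pixels.
#' @param cellsize coarse pixel size, metres.
#' @param subpixel_factor fine land-cover cells per pixel edge (>= 1).
#' @param class_emissivities named numeric(8) in (0,1].
#' @param class_shares named numeric(8) of target areal shares, summing to 1.
#'   A zero share produces a scene without that class (flagged, not an error).
#' @param overpass_times local decimal hours of the simulated acquisitions.
#' @param sunrise,sunset local decimal hours bounding daytime.
#' @param gaf_slope canopy temperature change per unit green-area fraction
#'   during daytime (K; negative = cooling).
#' @param dtw_amplitude shoreline effect amplitude at distance 0 (K).
#' @param dtw_length_scale e-folding length of the shoreline effect (km).
#' @param bh_day_coeff,bh_night_coeff coefficients of `log(1 + BH)` applied
#'   to the canopy field in day and night respectively (K).
#' @param noise_sigma observation noise added to composed LST (K).
#' @param micro_sigma spatially correlated micro-scale variability added to
#'   every element truth field (K); 0 gives spatially constant class fields
#'   when all effects are off.
#' @param micro_length correlation length of that variability (pixels).
#' @param coastal logical; if TRUE water concentrates along one domain edge
#'   so distances to water span the full domain width.
#' @param street_tree_frac fraction of the tree cover placed as scattered
#'   street/yard trees inside the built fabric rather than in contiguous
#'   parks (default 0.15).
#' @param seed integer RNG seed; fixed seed gives bit-identical scenes.
#' @return A `scene_config` list.
#' @export
scene_config <- function(grid_rows = 100, grid_cols = 100, cellsize = 70,
                         subpixel_factor = 10,
                         class_emissivities = default_emissivities(),
                         class_shares = c(tree = 0.22, grass = 0.07,
                                          bare = 0.03, water = 0.10,
                                          building = 0.25, road = 0.18,
                                          imperv = 0.12, rail = 0.03),
                         overpass_times = seq(1, 23, by = 2),
                         sunrise = 5.5, sunset = 20.5,
                         gaf_slope = -4, dtw_amplitude = -2,
                         dtw_length_scale = 0.5,
                         bh_day_coeff = -0.45, bh_night_coeff = 0.35,
                         noise_sigma = 0.5, micro_sigma = 0.3,
                         micro_length = 3, coastal = TRUE,
                         street_tree_frac = 0.15, seed = 1L) {
  stopifnot(grid_rows >= 1, grid_cols >= 1,
            subpixel_factor >= 1, subpixel_factor == round(subpixel_factor),
            length(class_emissivities) == 8,
            all(class_emissivities > 0), all(class_emissivities <= 1),
            length(class_shares) == 8, all(class_shares >= 0),
            abs(sum(class_shares) - 1) < 1e-8,
            noise_sigma >= 0, micro_sigma >= 0,
            street_tree_frac >= 0, street_tree_frac <= 1,
            dtw_length_scale > 0, micro_length > 0,
            sunrise < sunset)
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 cellsize = cellsize,
                 subpixel_factor = as.integer(subpixel_factor),
                 class_emissivities = class_emissivities,
                 class_shares = class_shares,
                 overpass_times = overpass_times,
                 sunrise = sunrise, sunset = sunset,
                 gaf_slope = gaf_slope, dtw_amplitude = dtw_amplitude,
                 dtw_length_scale = dtw_length_scale,
                 bh_day_coeff = bh_day_coeff, bh_night_coeff = bh_night_coeff,
                 noise_sigma = noise_sigma, micro_sigma = micro_sigma,
                 micro_length = micro_length, coastal = coastal,
                 street_tree_frac = street_tree_frac,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# Smooth standardized Gaussian random field via FFT filtering of white
# noise (periodic boundaries). L is the smoothing length in cells; L = 0
# returns plain white noise.
.gfield <- function(nr, nc, L) {
  w <- matrix(rnorm(nr * nc), nr, nc)
  if (L <= 0 || (nr == 1 && nc == 1)) return(w)
  fi <- c(0:(nr %/% 2), if (nr > 2) -((ceiling(nr / 2) - 1):1)) / nr
  fj <- c(0:(nc %/% 2), if (nc > 2) -((ceiling(nc / 2) - 1):1)) / nc
  att <- exp(-2 * pi^2 * L^2 * outer(fi^2, fj^2, "+"))
  s <- Re(fft(fft(w) * att, inverse = TRUE)) / (nr * nc)
  (s - mean(s)) / stats::sd(s)
}

# Nearest-neighbour upsampling by integer factor.
.upsample <- function(m, f) {
  if (f == 1) return(m)
  m[rep(seq_len(nrow(m)), each = f), rep(seq_len(ncol(m)), each = f)]
}

#' Generate a synthetic urban scene
#'
#' Builds a fine-grid categorical land-cover map from thresholded smoothed
#' random fields (contiguous parks, water bodies along a coast plus inland
#' ponds, built blocks split into building/road/impervious/rail), a
#' building-height layer on building cells, and derives the coarse-grid
#' products: class fraction stack, area-weighted building height, water
#' mask, distance to bluespace, green-area fraction, and a 2 x 3 zone
#' partition (borough analogue). Deterministic under the config seed.
#'
#' @param config a [scene_config()].
#' @return A `ct_scene` list with elements `config`, `class_map` (fine),
#'   `bh_fine`, `fractions` (rows x cols x 8), `bh`, `water_mask`, `dtw`
#'   (km), `gaf`, `zone_id`, and `class_flags` (TRUE where a class ended up
#'   empty).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  nr <- config$grid_rows; nc <- config$grid_cols
  f <- config$subpixel_factor
  nrf <- nr * f; ncf <- nc * f

  g_px <- .gfield(nr, nc, 5)     # greenness (park scale ~350 m)
  w_px <- .gfield(nr, nc, 6)     # wetness
  b_px <- .gfield(nr, nc, 4)     # built intensity
  h_px <- .gfield(nr, nc, 6)     # building height driver
  v_px <- .gfield(nr, nc, 3)     # vegetation type (tree vs grass vs bare)

  g_f <- .upsample(g_px, f) + 0.25 * matrix(rnorm(nrf * ncf), nrf, ncf)
  wet <- w_px
  if (config$coastal) {
    coast <- matrix(rep(seq(-1.2, 1.2, length.out = nc), each = nr), nr, nc)
    wet <- 0.9 * coast + w_px
  }
  wet_f <- .upsample(wet, f) + 0.10 * matrix(rnorm(nrf * ncf), nrf, ncf)
  b_f <- .upsample(b_px, f) + 0.25 * matrix(rnorm(nrf * ncf), nrf, ncf)
  v_f <- .upsample(v_px, f) + 0.35 * matrix(rnorm(nrf * ncf), nrf, ncf)

  shares <- config$class_shares
  n_fine <- nrf * ncf
  class_map <- matrix(0L, nrf, ncf)

  # water first, by wetness rank
  n_water <- round(shares[["water"]] * n_fine)
  if (n_water > 0) {
    ord <- order(wet_f, decreasing = TRUE)[seq_len(n_water)]
    class_map[ord] <- 4L
  }
  # natural (vegetated/bare) cells by total greenness; the split into
  # tree/grass/bare follows an independent vegetation-type field so grass
  # patches are not confined to tree-patch margins (lawns and parks are
  # distinct landscape elements, which also keeps the class fractions
  # identifiable within solve windows)
  land <- which(class_map == 0L)
  land_shares <- shares[c("tree", "grass", "bare")] / sum(shares[-4])
  n_nat <- round(sum(land_shares) * length(land))
  nat <- land[order(g_f[land], decreasing = TRUE)[seq_len(n_nat)]]
  ord_nat <- nat[order(v_f[nat], decreasing = TRUE)]
  n_tree <- round(land_shares[["tree"]] * length(land))
  n_grass <- round(land_shares[["grass"]] * length(land))
  pos <- 0L
  for (cl in list(c(1L, n_tree), c(2L, n_grass),
                  c(3L, n_nat - n_tree - n_grass))) {
    if (cl[2] > 0) class_map[ord_nat[pos + seq_len(cl[2])]] <- cl[1]
    pos <- pos + cl[2]
  }
  built <- which(class_map == 0L)
  bs <- shares[c("building", "road", "imperv", "rail")]
  bs <- if (sum(bs) > 0) bs / sum(bs) else bs
  ord_built <- built[order(b_f[built], decreasing = TRUE)]
  n_b <- round(bs[["building"]] * length(built))
  n_r <- round(bs[["road"]] * length(built))
  n_i <- round(bs[["imperv"]] * length(built))
  pos <- 0L
  for (cl in list(c(5L, n_b), c(6L, n_r), c(7L, n_i))) {
    if (cl[2] > 0) class_map[ord_built[pos + seq_len(cl[2])]] <- cl[1]
    pos <- pos + cl[2]
  }
  rest <- which(class_map == 0L)
  if (length(rest)) class_map[rest] <- 8L
  if (sum(shares[c("building", "road", "imperv", "rail")]) == 0 &&
      length(rest)) class_map[rest] <- 1L  # degenerate all-natural config

  # street trees: a share of the tree cover is scattered through the built
  # fabric (street and yard trees) rather than clustered in parks; swap
  # labels with the least-green park-tree cells so class shares are kept
  if (config$street_tree_frac > 0 && n_tree > 0) {
    built_cells <- which(matrix(class_map %in% c(5L, 6L, 7L),
                                nrf, ncf))
    tree_cells <- which(class_map == 1L)
    n_street <- min(round(config$street_tree_frac * n_tree),
                    length(built_cells), length(tree_cells))
    if (n_street > 0) {
      take <- sample(built_cells, n_street)
      give <- tree_cells[order(g_f[tree_cells])[seq_len(n_street)]]
      class_map[give] <- class_map[take]
      class_map[take] <- 1L
    }
  }

  class_flags <- setNames(tabulate(class_map, 8L) == 0L, ct_classes())
  if (any(class_flags))
    warning("empty class(es) in generated scene: ",
            paste(ct_classes()[class_flags], collapse = ", "))

  # building heights: lognormal around a smooth field, on building cells
  hf <- .upsample(h_px, f)
  bh_fine <- matrix(0, nrf, ncf)
  bcells <- class_map == 5L
  if (any(bcells)) {
    lh <- 2.4 + 1.0 * hf[bcells] + 0.25 * rnorm(sum(bcells))
    bh_fine[bcells] <- pmin(pmax(exp(lh), 3), 380)
  }

  fractions <- aggregate_fractions(class_map, f)
  bh <- area_weighted_bh(bh_fine, bcells, f)
  water_mask <- fractions[, , "water"] > 0.5
  dtw <- suppressWarnings(
    distance_to_bluespace(water_mask, cellsize = config$cellsize))
  gaf <- fractions[, , "tree"] + fractions[, , "grass"]
  zone_id <- matrix(0L, nr, nc)
  zi <- pmin((row(zone_id) - 1L) %/% max(1L, ceiling(nr / 2)), 1L)
  zj <- pmin((col(zone_id) - 1L) %/% max(1L, ceiling(nc / 3)), 2L)
  zone_id[] <- 1L + zi * 3L + zj

  structure(list(config = config, class_map = class_map, bh_fine = bh_fine,
                 fractions = fractions, bh = bh, water_mask = water_mask,
                 dtw = dtw, gaf = gaf, zone_id = zone_id,
                 class_flags = class_flags),
            class = "ct_scene")
}

#' @export
print.ct_scene <- function(x, ...) {
  cat(sprintf("<ct_scene> %d x %d pixels (x%d sub-pixel), %.1f%% water\n",
              x$config$grid_rows, x$config$grid_cols,
              x$config$subpixel_factor, 100 * mean(x$water_mask)))
  invisible(x)
}

# Diurnal base temperature per class: harmonic between a night minimum
# (01:30) and afternoon peak (13:30). Peak/night levels mirror typical
# summer urban element orderings: man-made surfaces warmest at midday,
# roads warmest among them at night, water nearly flat diurnally.
.base_temps <- function(hour) {
  peak <- c(tree = 301.5, grass = 302.0, bare = 304.5, water = 297.0,
            building = 305.4, road = 304.3, imperv = 304.6, rail = 304.4)
  night <- c(tree = 290.0, grass = 290.5, bare = 290.8, water = 291.0,
             building = 290.4, road = 291.4, imperv = 291.0, rail = 291.2)
  mid <- (peak + night) / 2
  amp <- (peak - night) / 2
  mid + amp * cos(2 * pi * (hour - 13.5) / 24)
}

#' Inject ground-truth element temperature fields for one overpass
#'
#' Builds per-class temperature fields at the coarse grid for a given local
#' hour: a class-specific diurnal base level, plus the configured
#' environmental effects applied to the tree-canopy field — during daytime
#' a green-area-fraction cooling (`gaf_slope * GAF`), a shoreline cooling
#' (`dtw_amplitude * exp(-DTW / L)`), and building-shadow cooling
#' (`bh_day_coeff * log(1 + BH)`), all modulated by a solar half-sine
#' peaking at mid-day; at night a `bh_night_coeff * log(1 + BH)` warming —
#' plus spatially correlated micro-variability on every class. Every
#' coefficient actually applied is recorded in the `"injected"` attribute
#' for recovery tests.
#'
#' @param scene a `ct_scene` from [generate_scene()].
#' @param hour local decimal hour of the overpass.
#' @return rows x cols x 8 array of truth temperatures (K) with attribute
#'   `"injected"`.
#' @export
inject_truth_temperatures <- function(scene, hour) {
  cfg <- scene$config
  nr <- cfg$grid_rows; nc <- cfg$grid_cols
  base <- .base_temps(hour)
  is_day <- hour > cfg$sunrise & hour < cfg$sunset
  w <- if (is_day) sin(pi * (hour - cfg$sunrise) / (cfg$sunset - cfg$sunrise)) else 0
  truth <- array(0, c(nr, nc, 8), dimnames = list(NULL, NULL, ct_classes()))
  set.seed(cfg$seed * 1000L + as.integer(round(hour * 10)) %% 997L)
  for (k in 1:8) {
    fld <- matrix(base[k], nr, nc)
    if (cfg$micro_sigma > 0)
      fld <- fld + cfg$micro_sigma * .gfield(nr, nc, cfg$micro_length)
    truth[, , k] <- fld
  }
  dtw_term <- exp(-scene$dtw / cfg$dtw_length_scale)
  dtw_term[!is.finite(scene$dtw)] <- 0
  eff <- list(hour = hour, day = is_day, day_weight = w,
              gaf_slope = w * cfg$gaf_slope,
              dtw_amplitude = w * cfg$dtw_amplitude,
              dtw_length_scale = cfg$dtw_length_scale,
              bh_coeff = if (is_day) w * cfg$bh_day_coeff else cfg$bh_night_coeff)
  truth[, , "tree"] <- truth[, , "tree"] +
    eff$gaf_slope * scene$gaf +
    eff$dtw_amplitude * dtw_term +
    eff$bh_coeff * log1p(scene$bh)
  attr(truth, "injected") <- eff
  truth
}

#' Compose a synthetic LST observation from element truth (forward model)
#'
#' Mixes per-class truth temperatures into a pixel LST through the
#' emissivity-weighted fourth-power radiance balance: the pixel radiance is
#' the fraction-weighted sum of `emis_k * f_k * T_k^4`, the pixel emissivity
#' the fraction-weighted mean of class emissivities, and
#' `LST = (radiance / emissivity)^(1/4)`. Gaussian observation noise is
#' added in Kelvin.
#'
#' @param truth rows x cols x 8 truth array (K), e.g. from
#'   [inject_truth_temperatures()].
#' @param fractions rows x cols x 8 fraction stack; each pixel must sum to 1.
#' @param emissivities numeric(8) class emissivities.
#' @param noise_sigma observation noise SD (K).
#' @param cellsize pixel size (m), carried into the output raster.
#' @param time local hour metadata for the output raster.
#' @param seed optional integer; if given, seeds the noise draw.
#' @return An [lst_raster()].
#' @export
forward_compose <- function(truth, fractions, emissivities,
                            noise_sigma = 0, cellsize = 70,
                            time = NA_real_, seed = NULL) {
  stopifnot(length(dim(truth)) == 3, dim(truth)[3] == 8,
            all(dim(truth) == dim(fractions)),
            length(emissivities) == 8)
  fsum <- apply(fractions, c(1, 2), sum)
  stopifnot(max(abs(fsum - 1)) < 1e-6)
  nr <- dim(truth)[1]; nc <- dim(truth)[2]
  rad <- matrix(0, nr, nc)
  eps_px <- matrix(0, nr, nc)
  for (k in 1:8) {
    fk <- fractions[, , k]
    tk4 <- truth[, , k]^4
    tk4[fk == 0] <- 0  # absent classes contribute nothing
    rad <- rad + emissivities[k] * fk * tk4
    eps_px <- eps_px + emissivities[k] * fk
  }
  radicand <- rad / eps_px
  stopifnot(all(radicand > 0))
  lst <- radicand^0.25
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    lst <- lst + matrix(rnorm(nr * nc, 0, noise_sigma), nr, nc)
  }
  lst_raster(lst, eps_px, cellsize = cellsize, time = time)
}

#' Simulate one overpass of a scene
#'
#' Convenience wrapper: injects truth temperatures for the hour and
#' composes the corresponding noisy LST observation.
#'
#' @param scene a `ct_scene`.
#' @param hour local decimal hour.
#' @param noise_sigma observation noise (defaults to the config value).
#' @param seed optional seed for the observation noise.
#' @return List with `truth` (array) and `lst` ([lst_raster()]).
#' @export
scene_overpass <- function(scene, hour,
                           noise_sigma = scene$config$noise_sigma,
                           seed = NULL) {
  truth <- inject_truth_temperatures(scene, hour)
  lst <- forward_compose(truth, scene$fractions,
                         scene$config$class_emissivities,
                         noise_sigma = noise_sigma,
                         cellsize = scene$config$cellsize,
                         time = hour, seed = seed)
  list(truth = truth, lst = lst)
}

#' Make a field (or truth stack) constant on square tiles
#'
#' Replaces every `block` x `block` tile by its mean, band by band. Used to
#' build scenes whose element truth is exactly constant at the solver's
#' window scale.
#'
#' @param x matrix or rows x cols x k array; dimensions must be divisible
#'   by `block`.
#' @param block tile edge in pixels.
#' @return Object of the same shape.
#' @export
tile_constant <- function(x, block = 5) {
  one <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    stopifnot(nr %% block == 0, nc %% block == 0)
    bi <- (row(m) - 1L) %/% block + 1L
    bj <- (col(m) - 1L) %/% block + 1L
    g <- bi + (bj - 1L) * (nr %/% block)
    mu <- tapply(as.vector(m), as.vector(g), mean)
    matrix(mu[g], nr, nc)
  }
  if (is.matrix(x)) return(one(x))
  stopifnot(length(dim(x)) == 3)
  out <- x
  for (k in seq_len(dim(x)[3])) out[, , k] <- one(x[, , k])
  out
}

#' Serialize a scene config to JSON
#'
#' @param config a [scene_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scene_config <- function(config, path) {
  x <- unclass(config)
  # keep element names: jsonlite drops names of atomic vectors
  for (nm in c("class_emissivities", "class_shares"))
    x[[nm]] <- as.list(x[[nm]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a scene config written by [write_scene_config()]
#'
#' @param path JSON path.
#' @return A [scene_config()].
#' @export
read_scene_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("class_emissivities", "class_shares"))
    x[[nm]] <- unlist(x[[nm]])
  do.call(scene_config, x)
}
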