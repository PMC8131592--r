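test_that("bvls matches unconstrained LS when interior and grid search at bounds", {
  set.seed(21)
  for (rep in 1:20) {
    n <- 20; p <- sample(2:4, 1)
    A <- matrix(runif(n * p, 0.1, 1), n, p)
    x_true <- runif(p, 0.3, 0.7)
    y <- as.vector(A %*% x_true) + rnorm(n, 0, 0.01)
    sol <- bvls(A, y, 0, 1)
    ref <- qr.solve(A, y)
    if (all(ref > 0 & ref < 1)) {
      expect_equal(sol$x, as.vector(ref), tolerance = 1e-9)
      expect_false(any(sol$bound_active))
    }
    # force an active bound and compare against tight clipped reference
    sol2 <- bvls(A, y, 0, max(ref) * 0.9)
    expect_true(all(sol2$x <= max(ref) * 0.9 + 1e-12))
    expect_true(all(sol2$x >= -1e-12))
  }
})

test_that("a pure window reproduces its own LST and leaves other classes NaN", {
  w <- list(lst = rep(300, 25), emis = rep(1, 25))
  fr <- matrix(0, 25, 8); fr[, 1] <- 1
  sol <- decompose_window(w$lst, w$emis, fr, rep(1, 8), 280, 320)
  expect_equal(sol$temps[1], 300, tolerance = 1e-9)
  expect_true(all(is.na(sol$temps[-1])))
  expect_lt(sol$residual_K, 1e-9)
  expect_equal(sol$flag, "ok")
})

test_that("noise-free windows recover multi-class truth and match grid search", {
  emis <- default_emissivities()
  w <- make_window(active = c(1, 6), truth = c(295, 310), seed = 2)
  sol <- decompose_window(w$lst, w$emis, w$fr, emis, 280, 320)
  expect_equal(sol$temps[1], 295, tolerance = 1e-3)
  expect_equal(sol$temps[6], 310, tolerance = 1e-3)

  # dense 2-D grid-search oracle on the same objective
  A <- sweep(w$fr[, c(1, 6)], 2, emis[c(1, 6)], `*`)
  y <- w$emis * w$lst^4
  gs <- grid_search_window(A, y, 280, 320)
  expect_equal(sol$temps[c(1, 6)], gs, tolerance = 0.02, ignore_attr = TRUE)
})

test_that("truth beyond the upper bound is clipped exactly to the bound", {
  emis <- default_emissivities()
  w <- make_window(active = c(1, 6), truth = c(295, 325), seed = 3)
  sol <- decompose_window(w$lst, w$emis, w$fr, emis, 280, 320)  # t_max 320 < 325
  expect_equal(sol$temps[6], 320, tolerance = 1e-9)
  expect_true(sol$bound_active[6])
  # the clipped class's unmet radiance spills into the free class, which
  # stays feasible and absorbs the excess
  expect_gte(sol$temps[1], 295)
  expect_lte(sol$temps[1], 320)
})

test_that("windows with fewer than 8 usable pixels are flagged unsolved", {
  fr <- matrix(0, 5, 8); fr[, 1] <- 1
  sol <- decompose_window(rep(300, 5), rep(1, 5), fr, rep(1, 8), 280, 320)
  expect_true(all(is.na(sol$temps)))
  expect_equal(sol$flag, "too_few_pixels")
})

test_that("a constant image decomposes to the constant everywhere solved", {
  cfg <- scene_config(grid_rows = 20, grid_cols = 20, seed = 8,
                      gaf_slope = 0, dtw_amplitude = 0, bh_day_coeff = 0,
                      bh_night_coeff = 0, micro_sigma = 0, noise_sigma = 0)
  sc <- generate_scene(cfg)
  truth <- inject_truth_temperatures(sc, 13.5)
  truth[] <- 300                        # identical element temperatures
  lst <- forward_compose(truth, sc$fractions, cfg$class_emissivities)
  expect_equal(max(abs(lst$lst - 300)), 0, tolerance = 1e-9)
  st <- decompose_image(lst, sc$fractions, cfg$class_emissivities,
                        bounds = c(280, 320))
  devs <- abs(st$temps - 300)[st$solved & rep(st$flag == "ok", 8)]
  expect_lt(max(devs), 1e-6)
})

test_that("solved temperatures respect bounds and the window radiance balance", {
  sc <- small_scene()
  ov <- scene_overpass(sc, 13.5, noise_sigma = 0.5, seed = 99)
  st <- decompose_image(ov$lst, sc$fractions, sc$config$class_emissivities)
  solved_vals <- st$temps[st$solved]
  expect_true(all(solved_vals >= st$bounds[1] - 1e-6))
  expect_true(all(solved_vals <= st$bounds[2] + 1e-6))

  # conservation: mean solved radiance + mean residual = mean observed
  # radiance, per window (normal-equation bookkeeping identity)
  emis <- sc$config$class_emissivities
  frmat <- matrix(sc$fractions, 40 * 40, 8)
  set.seed(5)
  for (rep in 1:25) {
    i <- sample(3:38, 1); j <- sample(3:38, 1)
    idx <- as.vector(outer((i - 2):(i + 2), ((j - 3):(j + 1)) * 40, `+`))
    sol <- decompose_window(ov$lst$lst[idx], ov$lst$emissivity[idx],
                            frmat[idx, ], emis, st$bounds[1], st$bounds[2],
                            min_fraction = 0)
    keep <- !is.na(sol$temps)
    A <- sweep(frmat[idx, keep, drop = FALSE], 2, emis[keep], `*`)
    y <- ov$lst$emissivity[idx] * ov$lst$lst[idx]^4
    fitted <- as.vector(A %*% sol$temps[keep]^4)
    expect_equal(mean(fitted) + mean(y - fitted), mean(y), tolerance = 1e-8)
    # and the identity written with window-mean fractions
    lhs <- sum(emis[keep] * colMeans(frmat[idx, keep, drop = FALSE]) *
                 sol$temps[keep]^4) + mean(y - fitted)
    expect_equal(lhs, mean(y), tolerance = max(1e-9 * mean(y), 1e-6))
  }
})

test_that("recovery error grows monotonically with observation noise", {
  cfg <- scene_config(grid_rows = 30, grid_cols = 30, seed = 14)
  sc <- generate_scene(cfg)
  truth <- tile_constant(inject_truth_temperatures(sc, 13.5), 5)
  cen <- seq(3, 28, by = 5)
  rmse_at <- function(sigma) {
    errs <- c()
    for (s in 1:4) {
      lst <- forward_compose(truth, sc$fractions, cfg$class_emissivities,
                             noise_sigma = sigma, time = 13.5, seed = 500 + s)
      st <- decompose_image(lst, sc$fractions, cfg$class_emissivities,
                            bounds = c(273, 333))
      e <- (st$temps - truth)[cen, cen, ]
      ok <- st$solved[cen, cen, ] & rep(st$flag[cen, cen] == "ok", 8)
      errs <- c(errs, e[ok])
    }
    sqrt(mean(errs^2))
  }
  r <- vapply(c(0, 0.25, 0.75), rmse_at, 0)
  expect_lt(r[1], 1e-6)
  expect_gt(r[2], r[1])
  expect_gt(r[3], r[2] * 0.9)  # allow Monte-Carlo slack at the top level
})

test_that("kernel sensitivity prefers the kernel matching the truth scale", {
  # four active classes so the 3x3 kernel (9 pixels) stays well-posed
  cfg <- scene_config(grid_rows = 27, grid_cols = 27, seed = 6,
                      noise_sigma = 0,
                      class_shares = c(tree = 0.35, grass = 0.15, bare = 0,
                                       water = 0, building = 0.3,
                                       road = 0.2, imperv = 0, rail = 0))
  sc <- suppressWarnings(generate_scene(cfg))
  # truth constant per 3x3 tiles: where the window matches the tiling
  # (tile centers) the 3x3 kernel is exact and must beat the straddling 5x5
  truth3 <- tile_constant(inject_truth_temperatures(sc, 13.5), 3)
  lst <- forward_compose(truth3, sc$fractions, cfg$class_emissivities,
                         time = 13.5)
  cen <- seq(2, 26, by = 3)
  rmse_k <- function(kern) {
    st <- decompose_image(lst, sc$fractions, cfg$class_emissivities,
                          bounds = c(273, 333), kernel = kern)
    e <- (st$temps - truth3)[cen, cen, ]
    ok <- st$solved[cen, cen, ] & rep(st$flag[cen, cen] == "ok", 8)
    sqrt(mean(e[ok]^2))
  }
  r3 <- rmse_k(3)
  expect_lt(r3, rmse_k(5))
  expect_lt(r3, 1e-6)

  # globally constant truth: all kernels near-exact (ok windows)
  truth_c <- truth3; truth_c[] <- 301
  lst_c <- forward_compose(truth_c, sc$fractions, cfg$class_emissivities,
                           time = 13.5)
  for (kern in c(3, 5)) {
    st <- decompose_image(lst_c, sc$fractions, cfg$class_emissivities,
                          bounds = c(273, 333), kernel = kern)
    ok <- st$solved & rep(st$flag == "ok", 8)
    expect_lt(max(abs(st$temps - 301)[ok]), 1e-6)
  }

  # the reporting path produces one row per kernel
  tab <- kernel_sensitivity(sc, kernels = c(3, 5), noise_sigma = 0,
                            bounds = c(273, 333))
  expect_equal(tab$kernel, c(3, 5))
  expect_true(all(tab$n_solves > 0))
})

test_that("canopy masking follows the tree-fraction threshold monotonically", {
  sc <- small_scene()
  ov <- scene_overpass(sc, 13.5, noise_sigma = 0.3, seed = 1)
  st <- decompose_image(ov$lst, sc$fractions, sc$config$class_emissivities)
  c05 <- canopy_map(st, sc$fractions, 0.05)
  c20 <- canopy_map(st, sc$fractions, 0.20)
  expect_lt(sum(is.finite(c20)), sum(is.finite(c05)))
  expect_true(all(is.na(c05[sc$fractions[, , "tree"] == 0])))
  full <- which(sc$fractions[, , "tree"] == 1 & is.finite(st$temps[, , 1]))
  expect_equal(c05[full], st$temps[, , "tree"][full])
})
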