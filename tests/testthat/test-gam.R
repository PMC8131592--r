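# Small direct-constructed neighborhood tables: the GAM layer is exercised
# against known response constructions without running the full image
# pipeline (that is done in the acceptance suite).
make_table <- function(n = 600, seed = 1, response = function(g, d, b) 0,
                       noise = 0.3) {
  set.seed(seed)
  gaf <- runif(n)
  dtw <- pmin(rexp(n, 1 / 1.5), 8)
  bh <- pmin(rexp(n, 1 / 12), 80)
  x <- runif(n, 0, 11); y <- runif(n, 0, 11)
  data.frame(delta_lst = response(gaf, dtw, bh) + rnorm(n, 0, noise),
             gaf = gaf, dtw = dtw, bh = bh, x = x, y = y,
             zone = 1L, n_pixels = 25L)
}

test_that("neighborhood aggregation takes block means and drops empty blocks", {
  set.seed(6)
  delta <- matrix(rnorm(100), 10, 10)
  gaf <- matrix(runif(100), 10, 10)
  dtw <- matrix(runif(100, 0, 5), 10, 10)
  bh <- matrix(runif(100, 0, 30), 10, 10)
  tab <- build_neighborhood_table(delta, gaf, dtw, bh, block = 5)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$delta_lst[1], mean(delta[1:5, 1:5]))
  expect_equal(tab$gaf[1], mean(gaf[1:5, 1:5]))
  expect_equal(tab$dtw[1], dtw[3, 3])          # centre-pixel evaluation
  expect_equal(tab$x[1], 0.5 * 5 * 70 / 1000)

  # NaN handling: block mean over valid members only; empty block dropped
  delta2 <- delta
  delta2[1:5, 1:5][sample(25, 20)] <- NA
  delta2[6:10, 1:5] <- NA
  tab2 <- build_neighborhood_table(delta2, gaf, dtw, bh, block = 5)
  expect_equal(nrow(tab2), 3)
  expect_equal(attr(tab2, "dropped"), 1L)
  v <- delta2[1:5, 1:5]
  expect_equal(tab2$delta_lst[1], mean(v[is.finite(v)]))

  # constant inputs give a single-valued table
  tabc <- build_neighborhood_table(matrix(1, 10, 10), gaf * 0 + 0.4,
                                   dtw * 0 + 2, bh * 0 + 10, block = 5)
  expect_true(all(tabc$delta_lst == 1))
})

test_that("an exact linear response is fitted almost perfectly", {
  tab <- make_table(400, seed = 3,
                    response = function(g, d, b) 2 - 3 * g, noise = 0)
  # REML may warn about step failure on a zero-residual fit; harmless here
  fit <- suppressWarnings(fit_attribution(tab, "city"))
  expect_gt(fit$deviance_explained, 0.999)
})

test_that("partial effects are centered over the training data", {
  tab <- make_table(500, seed = 4,
                    response = function(g, d, b) -4 * g - 2 * exp(-d / 0.5))
  fit <- fit_attribution(tab, "city")
  tm <- predict(fit$model, type = "terms")
  for (term in c("s(gaf)", "s(dtw)", "s(bh)")) {
    expect_lt(abs(mean(tm[, term])), 1e-6)
  }
})

test_that("MTEs recover injected effect magnitudes and closed forms", {
  tab <- make_table(1000, seed = 5,
                    response = function(g, d, b) -4 * g - 2 * exp(-d / 0.5),
                    noise = 0.3)
  fit <- fit_attribution(tab, "city")
  mg <- suppressWarnings(compute_mte(fit, "gaf", c(0, 1)))  # clipped to support
  expect_equal(mg$mte, 4, tolerance = 0.15)
  expect_equal(mg$direction, -1)
  expect_true(mg$significant)
  md <- suppressWarnings(compute_mte(fit, "dtw", c(0, 3)))
  expect_equal(md$mte, 2 * (1 - exp(-6)), tolerance = 0.15 * 2)
  expect_true(md$significant)
  # bh carries no signal: small, non-significant effect
  mb <- compute_mte(fit, "bh")
  expect_lt(mb$mte, 1)
})

test_that("a dropped constant covariate yields a zero MTE and a warning", {
  tab <- make_table(300, seed = 6,
                    response = function(g, d, b) -3 * g)
  tab$bh <- 12
  expect_warning(fit <- fit_attribution(tab, "city"), "constant")
  expect_false("bh" %in% fit$terms)
  mb <- compute_mte(fit, "bh")
  expect_equal(mb$mte, 0)
  expect_equal(mb$direction, 0L)
  expect_false(mb$significant)
})

test_that("pure-noise responses show near-zero structure at nominal error rates", {
  n_sig <- 0L; n_terms <- 0L; devs <- c()
  for (s in 1:20) {
    tab <- make_table(300, seed = 100 + s, noise = 1)
    fit <- fit_attribution(tab, "city")
    for (v in c("gaf", "dtw", "bh")) {
      m <- compute_mte(fit, v)
      n_terms <- n_terms + 1L
      if (m$significant) n_sig <- n_sig + 1L
    }
    devs <- c(devs, fit$deviance_explained)
  }
  expect_lt(n_sig / n_terms, 0.2)     # type-I rate near the nominal 0.05
  expect_lt(median(devs), 0.15)       # deviance explained near zero
})

test_that("a smooth GAF effect is recovered within its confidence band", {
  f_true <- function(g) -2 * g + 1.5 * sin(pi * g)
  tab <- make_table(800, seed = 7,
                    response = function(g, d, b) f_true(g), noise = 0.3)
  fit <- fit_attribution(tab, "city")
  grid <- seq(0.02, 0.98, length.out = 50)
  nd <- data.frame(gaf = grid, dtw = median(tab$dtw), bh = median(tab$bh),
                   x = mean(tab$x), y = mean(tab$y))
  pr <- predict(fit$model, nd, type = "terms", se.fit = TRUE,
                terms = "s(gaf)")
  truth_c <- f_true(grid) - mean(f_true(tab$gaf))   # centered truth
  covered <- abs(as.vector(pr$fit) - truth_c) <= 1.96 * as.vector(pr$se.fit) + 0.05
  expect_gte(mean(covered), 0.8)
})

test_that("adding the spatial smooth never decreases deviance explained", {
  tab <- make_table(500, seed = 8,
                    response = function(g, d, b) -3 * g + 0.5 * exp(-d))
  fit0 <- fit_attribution(tab, "city", spatial = FALSE)
  fit1 <- fit_attribution(tab, "city", spatial = TRUE)
  expect_gte(fit1$deviance_explained, fit0$deviance_explained - 1e-6)
})

test_that("zone-scale fits use the minimal near-planar spatial basis", {
  tab <- make_table(250, seed = 9,
                    response = function(g, d, b) -3 * g)
  # mgcv warns while raising k to the thin-plate minimum; that is the point
  fit <- suppressWarnings(fit_attribution(tab, "zone"))
  sxy <- fit$model$smooth[[which(vapply(fit$model$smooth, function(s)
    identical(s$term, c("x", "y")), TRUE))]]
  expect_lte(sxy$bs.dim, 4)  # thin-plate minimum (3-dim null space + 1)
  expect_s3_class(fit$model, "gam")
})

test_that("effect shares are percentages that permute with their inputs", {
  mk <- function(v, m) list(variable = v, mte = m)
  sh <- effect_share(list(mk("gaf", 6), mk("dtw", 3), mk("bh", 1)))
  expect_equal(unname(sh), c(60, 30, 10))
  expect_equal(sum(sh), 100)
  sh2 <- effect_share(list(mk("bh", 1), mk("gaf", 6), mk("dtw", 3)))
  expect_equal(sh2[["gaf"]], sh[["gaf"]])
  expect_equal(names(sh2), c("bh", "gaf", "dtw"))
  # single dominant factor
  sh3 <- effect_share(list(mk("gaf", 10), mk("dtw", 1e-9)))
  expect_gt(sh3[["gaf"]], 99.9)
  expect_error(effect_share(list(mk("gaf", 0), mk("dtw", 0))), "zero")
})
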