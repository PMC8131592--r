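#' Build the neighborhood table for GAM attribution
#'
#' Aggregates the canopy anomaly and the covariate grids to the
#' neighborhood analysis scale (`block` x `block` pixels, 350 m at the
#' default 70 m grid and block 5): anomaly, GAF and BH as block means over
#' available pixels, DTW evaluated at the block center pixel, zone as the
#' center pixel's label, and cell-center coordinates in km. Blocks with no
#' valid canopy pixel are dropped (their count is reported as an
#' attribute).
#'
#' @param delta an `anomaly_raster` (or matrix) of canopy anomalies.
#' @param gaf,dtw,bh numeric covariate matrices co-registered with `delta`.
#' @param zone_id integer matrix of zone labels (optional).
#' @param cellsize pixel size (m).
#' @param block neighborhood edge in pixels (default 5).
#' @return data.frame with columns `delta_lst`, `gaf`, `dtw`, `bh`, `x`,
#'   `y` (km), `zone`, `n_pixels`; attribute `"dropped"` counts empty
#'   blocks.
#' @export
build_neighborhood_table <- function(delta, gaf, dtw, bh, zone_id = NULL,
                                     cellsize = 70, block = 5) {
  m <- if (inherits(delta, "anomaly_raster")) delta$delta else delta
  stopifnot(all(dim(gaf) == dim(m)), all(dim(dtw) == dim(m)),
            all(dim(bh) == dim(m)))
  nr <- nrow(m) %/% block; nc <- ncol(m) %/% block
  rows <- vector("list", nr * nc)
  dropped <- 0L
  cen <- (block + 1L) %/% 2L
  for (bj in seq_len(nc)) for (bi in seq_len(nr)) {
    ri <- (bi - 1L) * block + seq_len(block)
    rj <- (bj - 1L) * block + seq_len(block)
    dv <- m[ri, rj]
    ok <- is.finite(dv)
    if (!any(ok)) { dropped <- dropped + 1L; next }
    ci <- ri[cen]; cj <- rj[cen]
    rows[[bi + (bj - 1L) * nr]] <- data.frame(
      delta_lst = mean(dv[ok]),
      gaf = mean(gaf[ri, rj]),
      dtw = dtw[ci, cj],
      bh = mean(bh[ri, rj]),
      x = (bj - 0.5) * block * cellsize / 1000,
      y = (bi - 0.5) * block * cellsize / 1000,
      zone = if (is.null(zone_id)) 1L else zone_id[ci, cj],
      n_pixels = sum(ok))
  }
  out <- do.call(rbind, rows)
  attr(out, "dropped") <- dropped
  out
}

#' Fit the canopy-anomaly attribution GAM
#'
#' Penalized-spline generalized additive model of the neighborhood canopy
#' anomaly on green-area fraction, distance to bluespace and building
#' height, with restricted basis dimensions, two tensor-product interaction
#' terms, and a coarse spatial smooth:
#' `delta ~ s(gaf, k=6) + s(dtw, k=6) + s(bh, k=3) + ti(gaf, dtw) +
#' ti(dtw, bh) + s(x, y, k=k_xy)` with `k_xy = 10` at city scale and the
#' minimal admissible `k_xy = 3` (a nearly planar surface) at zone scale.
#' Smoothing parameters are selected by REML. Covariates that are constant
#' (or absent, e.g. DTW all-infinite when no bluespace qualifies) are
#' dropped from the formula with a warning. Each overpass is fitted
#' independently.
#'
#' @param table data.frame from [build_neighborhood_table()].
#' @param scale `"city"` or `"zone"`.
#' @param spatial include the `s(x, y)` smooth (default TRUE; disabling it
#'   is mainly useful for nested-model comparisons).
#' @return A `gam_attribution` list: `model` (the mgcv fit), `terms`
#'   (kept smooth terms), `partial` (per-variable data.frame grids with
#'   centered partial effect `fit` and 95% CI), `deviance_explained`,
#'   `p_values`, `medians`, `centroid`, `n`.
#' @export
fit_attribution <- function(table, scale = c("city", "zone"),
                            spatial = TRUE) {
  scale <- match.arg(scale)
  stopifnot(all(c("delta_lst", "gaf", "dtw", "bh", "x", "y") %in%
                names(table)))
  d <- table[is.finite(table$delta_lst), , drop = FALSE]
  if (nrow(d) < 200 && scale == "city")
    warning("fewer than 200 neighborhoods at city scale; fit may be unstable")
  usable <- function(v) {
    z <- d[[v]]
    all(is.finite(z)) && stats::sd(z) > 0
  }
  have <- c(gaf = usable("gaf"), dtw = usable("dtw"), bh = usable("bh"))
  if (!all(have))
    warning("dropping constant/absent term(s): ",
            paste(names(have)[!have], collapse = ", "))
  k_xy <- if (scale == "city") 10 else 3
  parts <- c(
    if (have[["gaf"]]) "s(gaf, k = 6)",
    if (have[["dtw"]]) "s(dtw, k = 6)",
    if (have[["bh"]]) "s(bh, k = 3)",
    if (have[["gaf"]] && have[["dtw"]]) "ti(gaf, dtw, k = c(4, 4))",
    if (have[["dtw"]] && have[["bh"]]) "ti(dtw, bh, k = c(4, 3))",
    if (spatial) sprintf("s(x, y, k = %d)", k_xy))
  fml <- stats::as.formula(paste("delta_lst ~", paste(parts, collapse = " + ")))
  model <- mgcv::gam(fml, data = d, method = "REML")
  smry <- summary(model)
  pv <- smry$s.table[, "p-value"]
  meds <- vapply(c("gaf", "dtw", "bh"), function(v)
    stats::median(d[[v]][is.finite(d[[v]])]), 0)
  centroid <- c(x = mean(d$x), y = mean(d$y))
  partial <- list()
  for (v in names(have)[have]) {
    grid <- seq(min(d[[v]]), max(d[[v]]), length.out = 100)
    nd <- data.frame(gaf = meds[["gaf"]], dtw = meds[["dtw"]],
                     bh = meds[["bh"]], x = centroid[["x"]],
                     y = centroid[["y"]])
    nd <- nd[rep(1, length(grid)), , drop = FALSE]
    nd[[v]] <- grid
    term <- sprintf("s(%s)", v)
    pr <- predict(model, nd, type = "terms", se.fit = TRUE,
                  terms = term)
    partial[[v]] <- data.frame(value = grid,
                               fit = as.vector(pr$fit),
                               lower = as.vector(pr$fit - 1.96 * pr$se.fit),
                               upper = as.vector(pr$fit + 1.96 * pr$se.fit))
  }
  structure(list(model = model, terms = names(have)[have],
                 partial = partial,
                 deviance_explained = smry$dev.expl,
                 p_values = pv, medians = meds, centroid = centroid,
                 n = nrow(d), scale = scale),
            class = "gam_attribution")
}

#' @export
print.gam_attribution <- function(x, ...) {
  cat(sprintf("<gam_attribution> %s scale, n = %d, deviance explained %.1f%%\n",
              x$scale, x$n, 100 * x$deviance_explained))
  cat("  terms:", paste(x$terms, collapse = ", "), "\n")
  invisible(x)
}

#' Maximum temperature effect (MTE) of one covariate
#'
#' Predicts the model response over a grid of the covariate with the other
#' covariates held at their training medians and the spatial smooth at the
#' domain centroid; the MTE is the max minus min of that prediction over
#' the evaluation range (so interaction terms involving the covariate
#' contribute at the conditioning values). Ranges outside the observed
#' support are clipped with a warning. `direction` reports the sign of
#' (prediction at range top minus at range bottom).
#'
#' @param result a `gam_attribution` from [fit_attribution()].
#' @param variable one of `"gaf"`, `"dtw"`, `"bh"`.
#' @param range numeric(2) evaluation range in the variable's units;
#'   default the observed support.
#' @param n_grid grid resolution (default 200).
#' @return List: `variable`, `range`, `mte` (K, >= 0), `direction` (-1, 0,
#'   1), `significant` (smooth-term p < 0.05), `p_value`.
#' @export
compute_mte <- function(result, variable, range = NULL, n_grid = 200) {
  stopifnot(inherits(result, "gam_attribution"))
  if (!variable %in% result$terms) {
    return(list(variable = variable, range = c(NA_real_, NA_real_),
                mte = 0, direction = 0L, significant = FALSE,
                p_value = NA_real_))
  }
  d <- result$model$model
  support <- range(d[[variable]])
  if (is.null(range)) {
    range <- support
  } else {
    stopifnot(length(range) == 2, range[1] < range[2])
    if (range[1] < support[1] || range[2] > support[2]) {
      warning("requested range extends beyond data support; clipping")
      range <- c(max(range[1], support[1]), min(range[2], support[2]))
    }
  }
  grid <- seq(range[1], range[2], length.out = n_grid)
  nd <- data.frame(gaf = result$medians[["gaf"]],
                   dtw = result$medians[["dtw"]],
                   bh = result$medians[["bh"]],
                   x = result$centroid[["x"]], y = result$centroid[["y"]])
  nd <- nd[rep(1, n_grid), , drop = FALSE]
  nd[[variable]] <- grid
  pred <- as.vector(predict(result$model, nd))
  term <- sprintf("s(%s)", variable)
  pv <- result$p_values[grepl(paste0("\\(", variable, "\\)"),
                              names(result$p_values))]
  pv <- if (length(pv)) unname(pv[1]) else NA_real_
  list(variable = variable, range = range,
       mte = max(pred) - min(pred),
       direction = sign(pred[n_grid] - pred[1]),
       significant = is.finite(pv) && pv < 0.05,
       p_value = pv)
}

#' Relative shares of the maximum temperature effects
#'
#' Expresses each covariate's MTE as a percentage of the summed MTEs. This
#' is one interpretation of an effect decomposition — the shares quantify
#' relative effect ranges, not variance explained.
#'
#' @param mtes list of results from [compute_mte()] (at least 2).
#' @return Named numeric vector of percentages summing to 100.
#' @export
effect_share <- function(mtes) {
  stopifnot(length(mtes) >= 2)
  vals <- vapply(mtes, function(m) m$mte, 0)
  names(vals) <- vapply(mtes, function(m) m$variable, "")
  tot <- sum(vals)
  if (tot == 0) stop("all MTEs are zero; shares undefined")
  100 * vals / tot
}
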