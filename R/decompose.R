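#' Box-constrained linear least squares (BVLS)
#'
#' Solves `min ||A x - y||^2` subject to `lower <= x <= upper` with the
#' Stark-Parker bounded-variable active-set algorithm. The fast path solves
#' the unconstrained problem first and returns it when it is interior.
#' Intended for small, well-posed systems (here: up to 8 unknowns per
#' solve window).
#'
#' @param A numeric matrix (n x p, n >= p recommended).
#' @param y numeric vector length n.
#' @param lower,upper numeric bounds, length p or scalars.
#' @param tol feasibility/KKT tolerance on the scaled gradient.
#' @param max_iter iteration cap.
#' @return List with `x` (solution), `iterations`, and `bound_active`
#'   (logical, which variables sit on a bound).
#' @export
bvls <- function(A, y, lower, upper, tol = 1e-10, max_iter = 200L) {
  p <- ncol(A)
  lower <- rep_len(lower, p); upper <- rep_len(upper, p)
  stopifnot(all(lower < upper), nrow(A) == length(y))
  # fast path: unconstrained interior solution
  fit <- .lm.fit(A, y)
  x_un <- numeric(p)
  x_un[] <- NA_real_
  x_un[fit$pivot[seq_len(fit$rank)]] <- fit$coefficients[seq_len(fit$rank)]
  if (fit$rank == p && all(x_un >= lower & x_un <= upper)) {
    return(list(x = x_un, iterations = 0L,
                bound_active = rep(FALSE, p)))
  }
  scale <- max(abs(upper[is.finite(upper)]), 1)
  # state: -1 at lower, +1 at upper, 0 free
  state <- ifelse(abs(lower) <= abs(upper), -1L, 1L)
  x <- ifelse(state == -1L, lower, upper)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) break
    r <- y - A %*% x
    g <- crossprod(A, r)  # negative gradient direction of SSE/2
    kkt <- (state == -1L & g > tol * scale) |
           (state == 1L & g < -tol * scale)
    free <- state == 0L
    if (!any(kkt)) {
      if (!any(free)) break
      # free set is optimal already (checked below by inner convergence)
    }
    if (any(kkt)) {
      j <- which(kkt)[which.max(abs(g[kkt]))]
      state[j] <- 0L
    } else if (!any(free)) break
    # inner loop: solve on free set, clip along path to feasibility
    repeat {
      Fset <- which(state == 0L)
      if (!length(Fset)) break
      rhs <- y - A[, state != 0L, drop = FALSE] %*% x[state != 0L]
      sub <- .lm.fit(A[, Fset, drop = FALSE], rhs)
      z <- numeric(length(Fset))
      z[] <- NA_real_
      z[sub$pivot[seq_len(sub$rank)]] <- sub$coefficients[seq_len(sub$rank)]
      if (anyNA(z)) {  # rank deficient free set: pin an undetermined var
        bad <- Fset[is.na(z)][1L]
        state[bad] <- -1L
        x[bad] <- lower[bad]
        next
      }
      lo <- lower[Fset]; hi <- upper[Fset]
      if (all(z >= lo - tol * scale & z <= hi + tol * scale)) {
        x[Fset] <- pmin(pmax(z, lo), hi)
        break
      }
      # step from x[Fset] toward z, stop at first violated bound
      xf <- x[Fset]
      d <- z - xf
      alpha <- rep(1, length(Fset))
      below <- d < 0
      above <- d > 0
      alpha[below] <- pmin(1, (lo[below] - xf[below]) / d[below])
      alpha[above] <- pmin(1, (hi[above] - xf[above]) / d[above])
      a <- min(alpha)
      xf <- xf + a * d
      hit <- which(alpha <= a + 1e-15)
      x[Fset] <- xf
      for (h in hit) {
        jf <- Fset[h]
        if (d[h] < 0) { state[jf] <- -1L; x[jf] <- lower[jf] }
        else { state[jf] <- 1L; x[jf] <- upper[jf] }
      }
    }
    # convergence: no KKT violation anywhere and free set at LS optimum
    r <- y - A %*% x
    g <- crossprod(A, r)
    viol <- (state == -1L & g > tol * scale) |
            (state == 1L & g < -tol * scale) |
            (state == 0L & abs(g) > tol * scale * max(colSums(A^2)))
    if (!any(viol)) break
  }
  list(x = as.vector(x), iterations = iter,
       bound_active = state != 0L |
         abs(x - lower) < 1e-12 * scale | abs(upper - x) < 1e-12 * scale)
}

#' Solve one window of the element-temperature unmixing problem
#'
#' Builds, for the unmasked pixels of a window, the linear system in
#' fourth-power temperature space: design `A[p, k] = emis_k * f_k(p)`,
#' target `y[p] = emis(p) * LST(p)^4`, and solves
#' `min ||A x - y||^2` with `t_min^4 <= x_k <= t_max^4` over every class
#' present in the window (all eight unknowns when all are present, as the
#' constrained-rule formulation prescribes). Classes whose summed fraction
#' over the window is below `min_fraction * n_pixels` stay in the design —
#' removing their radiance would bias the identifiable classes — but are
#' reported as NaN, since their own estimate is not identifiable.
#' Variables are scaled by `t_max^4` before solving. If the design is
#' numerically rank deficient, the class with the smallest summed fraction
#' is dropped repeatedly (deterministic order) and the solve flagged.
#'
#' @param lst_w,emis_w numeric vectors (or matrices) of window LST (K) and
#'   pixel emissivity; NA entries are ignored.
#' @param fracs_w matrix n_pixels x 8 of class fractions for the same
#'   pixels (rows matching `lst_w` order).
#' @param class_emis numeric(8) class emissivities.
#' @param t_min,t_max solve bounds (K), `t_min < t_max`.
#' @param min_fraction identifiability threshold on the mean window
#'   fraction of a class (default 0.02).
#' @return List: `temps` numeric(8) (K, NA for dropped classes or failed
#'   windows), `residual_k4` RMS residual in emissivity-weighted K^4 units,
#'   `residual_K` the same expressed as an equivalent Kelvin error at the
#'   window's mean temperature, `flag` one of `"ok"`, `"rank_deficient"`,
#'   `"too_few_pixels"`, and `bound_active` logical(8).
#' @export
decompose_window <- function(lst_w, emis_w, fracs_w, class_emis,
                             t_min, t_max, min_fraction = 0.02) {
  stopifnot(t_min < t_max, length(class_emis) == 8)
  lst_w <- as.vector(lst_w); emis_w <- as.vector(emis_w)
  ok <- is.finite(lst_w) & is.finite(emis_w)
  temps <- rep(NA_real_, 8)
  out_fail <- list(temps = temps, residual_k4 = NA_real_,
                   residual_K = NA_real_, flag = "too_few_pixels",
                   bound_active = rep(FALSE, 8))
  if (sum(ok) < 8) return(out_fail)
  lst_w <- lst_w[ok]; emis_w <- emis_w[ok]
  fr <- fracs_w[ok, , drop = FALSE]
  n <- length(lst_w)
  fsum <- colSums(fr)
  keep <- which(fsum > 0)
  report <- fsum >= min_fraction * n
  if (!any(report)) return(out_fail)
  sc <- t_max^4
  y <- emis_w * lst_w^4 / sc
  flag <- "ok"
  repeat {
    A <- sweep(fr[, keep, drop = FALSE], 2, class_emis[keep], `*`)
    if (qr(A)$rank == length(keep)) break
    flag <- "rank_deficient"
    weakest <- keep[which.min(fsum[keep])]
    keep <- setdiff(keep, weakest)
    if (!length(keep)) {
      out_fail$flag <- "rank_deficient"
      return(out_fail)
    }
  }
  sol <- bvls(A, y, lower = (t_min / t_max)^4, upper = 1)
  temps[keep] <- (sol$x * sc)^0.25
  temps[!report] <- NA_real_
  res <- y - A %*% sol$x
  rms_k4 <- sqrt(mean(res^2)) * sc
  tbar <- mean(lst_w)
  active <- rep(FALSE, 8)
  active[keep] <- sol$bound_active
  list(temps = temps, residual_k4 = rms_k4,
       residual_K = rms_k4 / (4 * mean(emis_w) * tbar^3),
       flag = flag, bound_active = active)
}

#' Decompose an LST image into per-element temperature maps
#'
#' Slides an odd `kernel` x `kernel` window over the image with stride 1;
#' each window's bounded least-squares solution (see [decompose_window()])
#' is assigned to the window's center pixel. Border windows shrink to the
#' valid part of the image and are solved when at least 8 unmasked pixels
#' remain. Solve bounds default to the min and max of unmasked LST over
#' the whole image (the per-image constrained rule).
#'
#' @param lst an [lst_raster()].
#' @param fractions rows x cols x 8 fraction stack.
#' @param class_emis numeric(8) class emissivities.
#' @param bounds optional numeric(2) `c(t_min, t_max)` in K; default
#'   image-wide range of valid LST.
#' @param kernel odd window edge length >= 3 (default 5).
#' @param min_fraction identifiability threshold per window (default 0.02).
#' @return An `element_stack` list: `temps` (rows x cols x 8, K),
#'   `residual_K`, `residual_k4`, `solved` (logical rows x cols x 8),
#'   `flag` (character matrix), `bounds`, `kernel`, and the input `time`.
#' @export
decompose_image <- function(lst, fractions, class_emis,
                            bounds = NULL, kernel = 5, min_fraction = 0.02) {
  stopifnot(inherits(lst, "lst_raster"),
            kernel >= 3, kernel %% 2 == 1,
            length(dim(fractions)) == 3, dim(fractions)[3] == 8,
            all(dim(lst$lst) == dim(fractions)[1:2]))
  if (!any(lst$valid)) stop("fully masked image")
  if (is.null(bounds)) bounds <- range(lst$lst[lst$valid])
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  nr <- nrow(lst$lst); nc <- ncol(lst$lst)
  h <- (kernel - 1L) %/% 2L
  lvec <- lst$lst; lvec[!lst$valid] <- NA_real_
  evec <- lst$emissivity
  frmat <- matrix(fractions, nr * nc, 8)

  temps <- array(NA_real_, c(nr, nc, 8),
                 dimnames = list(NULL, NULL, ct_classes()))
  resK <- matrix(NA_real_, nr, nc)
  res4 <- matrix(NA_real_, nr, nc)
  flag <- matrix("unsolved", nr, nc)
  tmat <- matrix(NA_real_, nr * nc, 8)

  for (j in seq_len(nc)) {
    j0 <- max(1L, j - h); j1 <- min(nc, j + h)
    for (i in seq_len(nr)) {
      i0 <- max(1L, i - h); i1 <- min(nr, i + h)
      idx <- as.vector(outer(i0:i1, (j0:j1 - 1L) * nr, `+`))
      sol <- decompose_window(lvec[idx], evec[idx], frmat[idx, , drop = FALSE],
                              class_emis, bounds[1], bounds[2],
                              min_fraction = min_fraction)
      p <- i + (j - 1L) * nr
      tmat[p, ] <- sol$temps
      resK[p] <- sol$residual_K
      res4[p] <- sol$residual_k4
      flag[p] <- sol$flag
    }
  }
  temps[] <- tmat
  structure(list(temps = temps, residual_K = resK, residual_k4 = res4,
                 solved = !is.na(temps), flag = flag, bounds = bounds,
                 kernel = kernel, time = lst$time),
            class = "element_stack")
}

#' @export
print.element_stack <- function(x, ...) {
  cat(sprintf("<element_stack> %d x %d pixels, kernel %d, bounds [%.1f, %.1f] K\n",
              dim(x$temps)[1], dim(x$temps)[2], x$kernel,
              x$bounds[1], x$bounds[2]))
  cat(sprintf("  solved pixel-classes: %d; flagged windows: %d\n",
              sum(x$solved), sum(x$flag != "ok")))
  invisible(x)
}

#' Kernel-size sensitivity of the unmixing
#'
#' Runs the decomposition at several window sizes against a scene with
#' known truth and tabulates per-class RMSE, the mean residual, and the
#' number of solves (a runtime proxy).
#'
#' @param scene a `ct_scene`.
#' @param hour local overpass hour (default mid-day, 13.5).
#' @param kernels integer vector of odd window sizes.
#' @param noise_sigma observation noise for the simulated image (default
#'   from config).
#' @param bounds optional solve bounds, as in [decompose_image()].
#' @param seed seed for the observation noise.
#' @return data.frame: one row per kernel with `rmse_<class>` columns,
#'   `mean_residual_K` and `n_solves`.
#' @export
kernel_sensitivity <- function(scene, hour = 13.5, kernels = c(3, 5, 7, 9),
                               noise_sigma = scene$config$noise_sigma,
                               bounds = NULL, seed = 1L) {
  ov <- scene_overpass(scene, hour, noise_sigma = noise_sigma, seed = seed)
  rows <- lapply(kernels, function(k) {
    st <- decompose_image(ov$lst, scene$fractions,
                          scene$config$class_emissivities,
                          bounds = bounds, kernel = k)
    err <- st$temps - ov$truth
    rmse <- sapply(1:8, function(cl) {
      e <- err[, , cl][st$solved[, , cl]]
      if (length(e)) sqrt(mean(e^2)) else NA_real_
    })
    c(kernel = k, setNames(rmse, paste0("rmse_", ct_classes())),
      mean_residual_K = mean(st$residual_K, na.rm = TRUE),
      n_solves = sum(st$flag != "unsolved"))
  })
  as.data.frame(do.call(rbind, rows))
}

#' Canopy temperature map from a decomposed stack
#'
#' Tree-class solved temperature where the pixel's own tree fraction meets
#' the threshold; NaN-style NA elsewhere.
#'
#' @param stack an `element_stack` from [decompose_image()].
#' @param fractions the fraction stack used for the decomposition.
#' @param canopy_fraction_min minimum per-pixel tree fraction (default 0.05).
#' @return Numeric matrix (K) with NA outside the canopy mask.
#' @export
canopy_map <- function(stack, fractions, canopy_fraction_min = 0.05) {
  stopifnot(inherits(stack, "element_stack"))
  out <- stack$temps[, , "tree"]
  out[fractions[, , "tree"] < canopy_fraction_min] <- NA_real_
  out
}
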