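#' Aggregate a fine categorical map to per-pixel class fractions
#'
#' Counts fine cells of each surface class inside non-overlapping
#' `factor` x `factor` blocks and divides by the block area, matching the
#' footprint of the thermal grid. If the fine grid is not divisible by
#' `factor` it is cropped at the south/east edges with a warning.
#'
#' @param class_map integer matrix of class codes 1..8 (see [ct_classes()]).
#' @param factor integer >= 1, fine cells per coarse pixel edge.
#' @return rows x cols x 8 array of fractions in [0,1]; each pixel sums to 1.
#' @export
aggregate_fractions <- function(class_map, factor) {
  stopifnot(is.matrix(class_map), factor >= 1, factor == round(factor))
  codes <- unique(as.vector(class_map))
  codes <- codes[!is.na(codes)]
  bad <- setdiff(codes, 1:8)
  if (length(bad)) stop("unknown class code(s): ", paste(bad, collapse = ", "))
  nrf <- nrow(class_map); ncf <- ncol(class_map)
  nr <- nrf %/% factor; nc <- ncf %/% factor
  if (nr * factor != nrf || nc * factor != ncf) {
    warning("fine grid not divisible by factor; cropping to ",
            nr * factor, " x ", nc * factor)
    class_map <- class_map[seq_len(nr * factor), seq_len(nc * factor)]
  }
  out <- array(0, c(nr, nc, 8), dimnames = list(NULL, NULL, ct_classes()))
  # block row/col index of every fine cell
  bi <- (row(class_map) - 1L) %/% factor + 1L
  bj <- (col(class_map) - 1L) %/% factor + 1L
  pix <- bi + (bj - 1L) * nr
  for (k in 1:8) {
    cnt <- tabulate(pix[class_map == k], nbins = nr * nc)
    out[, , k] <- matrix(cnt, nr, nc) / factor^2
  }
  out
}

#' Area-weighted mean building height per coarse pixel
#'
#' Aggregates a fine-resolution height raster to the coarse grid, weighting
#' each building cell by its footprint area. By default the divisor is the
#' built area inside the block (the mean height of the buildings present);
#' `denominator = "total"` divides by the whole block area instead.
#' Blocks with no built cells get 0.
#'
#' @param bh_fine numeric matrix of heights (m), any value on non-built cells
#'   is ignored.
#' @param built_mask logical matrix, TRUE on building cells.
#' @param factor fine cells per coarse pixel edge.
#' @param denominator `"built"` (default) or `"total"`.
#' @return Matrix of heights (m) at the coarse resolution.
#' @export
area_weighted_bh <- function(bh_fine, built_mask, factor,
                             denominator = c("built", "total")) {
  denominator <- match.arg(denominator)
  stopifnot(is.matrix(bh_fine), all(dim(bh_fine) == dim(built_mask)))
  if (any(bh_fine[built_mask] < 0)) stop("negative building heights")
  nr <- nrow(bh_fine) %/% factor; nc <- ncol(bh_fine) %/% factor
  bh_fine <- bh_fine[seq_len(nr * factor), seq_len(nc * factor)]
  built_mask <- built_mask[seq_len(nr * factor), seq_len(nc * factor)]
  bi <- (row(bh_fine) - 1L) %/% factor + 1L
  bj <- (col(bh_fine) - 1L) %/% factor + 1L
  pix <- bi + (bj - 1L) * nr
  hsum <- tabulate(pix[built_mask], nbins = nr * nc)  # built cell counts
  wsum <- rep(0, nr * nc)
  idx <- pix[built_mask]
  if (length(idx))
    wsum <- as.vector(tapply(bh_fine[built_mask], factor(idx, levels = seq_len(nr * nc)), sum))
  wsum[is.na(wsum)] <- 0
  denom <- if (denominator == "built") hsum else rep(factor^2, nr * nc)
  out <- ifelse(denom > 0 & hsum > 0, wsum / denom, 0)
  matrix(out, nr, nc)
}

#' Label connected components of a logical mask
#'
#' Breadth-first labelling with 8-connectivity by default (diagonal
#' neighbours join), so diagonal water strips count as one waterbody.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix: 0 on background, component ids 1..n on TRUE cells.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.logical(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    di <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dj <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    di <- c(-1L, 1L, 0L, 0L); dj <- c(0L, 0L, -1L, 1L)
  }
  cur <- 0L
  todo <- which(mask)
  for (s in todo) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pi <- (p - 1L) %% nr + 1L
      pj <- (p - 1L) %/% nr + 1L
      ni <- pi + di; nj <- pj + dj
      ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
      q <- ni[ok] + (nj[ok] - 1L) * nr
      q <- q[mask[q] & lab[q] == 0L]
      if (length(q)) {
        lab[q] <- cur
        stack <- c(stack, q)
      }
    }
  }
  lab
}

# Exact 1-D squared Euclidean distance transform (lower envelope of
# parabolas, Felzenszwalb & Huttenlocher). f is the initial squared
# distance per sample; returns the transformed squared distances.
.edt1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Exact Euclidean distance transform of a mask
#'
#' Center-to-center distance from every cell to the nearest TRUE cell,
#' computed exactly with the two-pass separable parabola algorithm.
#'
#' @param mask logical matrix (targets are TRUE).
#' @return Numeric matrix of distances in cell units; `Inf` if the mask has
#'   no TRUE cell.
#' @export
distance_transform <- function(mask) {
  stopifnot(is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  BIG <- 1e12  # finite stand-in for +Inf to keep parabola arithmetic exact
  f <- matrix(BIG, nr, nc)
  f[mask] <- 0
  for (j in seq_len(nc)) f[, j] <- .edt1d(f[, j])
  for (i in seq_len(nr)) f[i, ] <- .edt1d(f[i, ])
  d <- sqrt(f)
  d[f >= BIG] <- Inf
  d
}

#' Distance to the nearest qualifying bluespace
#'
#' Removes connected water components (8-connectivity) with area not
#' exceeding `min_area_m2`, then computes the exact Euclidean
#' center-to-center distance from every cell to the nearest remaining water
#' cell, in kilometres. Water cells themselves get 0.
#'
#' @param water_mask logical matrix, TRUE on water.
#' @param cellsize cell size in metres.
#' @param min_area_m2 minimum waterbody area to qualify (strictly greater
#'   retained); default 500.
#' @return Numeric matrix of distances (km); all `Inf`, with a warning, if
#'   no waterbody qualifies.
#' @export
distance_to_bluespace <- function(water_mask, cellsize = 70,
                                  min_area_m2 = 500) {
  stopifnot(is.logical(water_mask))
  lab <- label_components(water_mask, connectivity = 8)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes * cellsize^2 > min_area_m2)
    qual <- matrix(lab %in% keep, nrow(water_mask), ncol(water_mask))
  } else {
    qual <- water_mask  # all FALSE
  }
  if (!any(qual)) {
    warning("no qualifying bluespace in scene; DTW is +Inf everywhere")
    return(matrix(Inf, nrow(water_mask), ncol(water_mask)))
  }
  distance_transform(qual) * cellsize / 1000
}
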