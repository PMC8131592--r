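#' Land-only domain mean LST
#'
#' Arithmetic mean of the observed pixel LST over land pixels, the scalar
#' reference used to form spatial anomalies. Water and nodata pixels are
#' excluded so strong waterbody thermal contrasts do not shift the
#' reference.
#'
#' @param lst an [lst_raster()].
#' @param land_mask logical matrix, TRUE on land pixels to include.
#' @return Scalar mean (K).
#' @export
domain_mean <- function(lst, land_mask) {
  stopifnot(inherits(lst, "lst_raster"),
            all(dim(land_mask) == dim(lst$lst)))
  use <- land_mask & lst$valid
  if (!any(use)) stop("empty land mask")
  mean(lst$lst[use])
}

#' Spatial anomaly of a canopy temperature map
#'
#' Subtracts the scalar domain-mean reference from the canopy map,
#' pixelwise; NA propagates. The reference and overpass time are stored
#' with the result.
#'
#' @param canopy numeric matrix of canopy temperatures (K), e.g. from
#'   [canopy_map()].
#' @param ref_mean scalar reference (K), e.g. from [domain_mean()].
#' @param time overpass local hour carried as metadata.
#' @return An `anomaly_raster`: list with `delta` (matrix, K),
#'   `reference_mean`, `time`.
#' @export
anomaly_map <- function(canopy, ref_mean, time = NA_real_) {
  stopifnot(is.matrix(canopy), is.numeric(ref_mean), length(ref_mean) == 1)
  structure(list(delta = canopy - ref_mean, reference_mean = ref_mean,
                 time = time),
            class = "anomaly_raster")
}

#' @export
print.anomaly_raster <- function(x, ...) {
  v <- x$delta[is.finite(x$delta)]
  cat(sprintf("<anomaly_raster> %d x %d, ref %.2f K, local time %s\n",
              nrow(x$delta), ncol(x$delta), x$reference_mean,
              format(x$time)))
  if (length(v))
    cat(sprintf("  delta mean %+.2f K, sd %.2f K over %d canopy pixels\n",
                mean(v), stats::sd(v), length(v)))
  invisible(x)
}
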