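#' Spatial mean and STD of an anomaly map
#'
#' Population (divide-by-n) standard deviation, the descriptive statistic
#' for a full map rather than a sample.
#'
#' @param delta an `anomaly_raster` or a plain numeric matrix.
#' @return List `mean`, `std`, `n` over finite pixels.
#' @export
spatial_stats <- function(delta) {
  m <- if (inherits(delta, "anomaly_raster")) delta$delta else delta
  v <- m[is.finite(m)]
  if (length(v) < 2) stop("need at least 2 valid pixels")
  mu <- mean(v)
  list(mean = mu, std = sqrt(mean((v - mu)^2)), n = length(v))
}

#' Canopy-vs-element temperature contrasts
#'
#' Pixelwise `T_k - T_tree` for each non-tree class over pixels where both
#' the class and the tree canopy were solved; positive means the element is
#' warmer than the canopy.
#'
#' @param stack an `element_stack` from [decompose_image()].
#' @return data.frame with one row per non-tree class: `class`, `mean`,
#'   `std` (population), `n`. Classes with no co-solved pixels get NA with
#'   a warning.
#' @export
element_contrast <- function(stack) {
  stopifnot(inherits(stack, "element_stack"))
  tree <- stack$temps[, , "tree"]
  cls <- setdiff(ct_classes(), "tree")
  rows <- lapply(cls, function(cl) {
    d <- stack$temps[, , cl] - tree
    d <- d[is.finite(d)]
    if (!length(d)) {
      warning("no co-solved pixels for class ", cl)
      return(data.frame(class = cl, mean = NA_real_, std = NA_real_, n = 0L))
    }
    mu <- mean(d)
    data.frame(class = cl, mean = mu, std = sqrt(mean((d - mu)^2)),
               n = length(d))
  })
  do.call(rbind, rows)
}

#' Zonal means of an anomaly map
#'
#' @param delta an `anomaly_raster` or matrix.
#' @param zone_id integer matrix of zone labels (borough analogue).
#' @return data.frame `zone`, `mean`, `n` (finite pixels per zone).
#' @export
zonal_mean <- function(delta, zone_id) {
  m <- if (inherits(delta, "anomaly_raster")) delta$delta else delta
  stopifnot(all(dim(zone_id) == dim(m)))
  ok <- is.finite(m)
  zs <- sort(unique(as.vector(zone_id)))
  rows <- lapply(zs, function(z) {
    v <- m[ok & zone_id == z]
    data.frame(zone = z,
               mean = if (length(v)) mean(v) else NA_real_,
               n = length(v))
  })
  do.call(rbind, rows)
}

#' Assemble the diurnal summary table
#'
#' One row per overpass, sorted by local time: spatial mean and STD of the
#' canopy anomaly, a day/night label from sunrise/sunset metadata, and the
#' per-class canopy contrasts (mean and STD) when element stacks are
#' supplied.
#'
#' @param products list of per-overpass lists, each with `delta` (an
#'   `anomaly_raster`) and optionally `stack` (an `element_stack`).
#' @param sunrise,sunset local decimal hours.
#' @return data.frame keyed by `time` with columns `mean_delta`,
#'   `std_delta`, `n`, `phase`, and `contrast_<class>` /
#'   `contrast_sd_<class>` for the 7 non-tree classes where stacks are
#'   present.
#' @export
build_diurnal_table <- function(products, sunrise, sunset) {
  stopifnot(length(products) >= 2)
  times <- vapply(products, function(p) as.numeric(p$delta$time), 0)
  if (anyDuplicated(times))
    warning("duplicate overpass times; keeping all rows")
  cls <- setdiff(ct_classes(), "tree")
  rows <- lapply(products, function(p) {
    st <- spatial_stats(p$delta)
    row <- data.frame(time = as.numeric(p$delta$time),
                      mean_delta = st$mean, std_delta = st$std, n = st$n,
                      phase = if (p$delta$time > sunrise &&
                                  p$delta$time < sunset) "day" else "night")
    if (!is.null(p$stack)) {
      ec <- element_contrast(p$stack)
      row[paste0("contrast_", ec$class)] <- ec$mean
      row[paste0("contrast_sd_", ec$class)] <- ec$std
    }
    row
  })
  out <- do.call(rbind, rows)
  out[order(out$time), , drop = FALSE]
}

#' Write / read a diurnal table as CSV
#'
#' Plain CSV with full-precision numerics so a round trip is lossless to
#' within double formatting (15 significant digits).
#'
#' @param table data.frame from [build_diurnal_table()].
#' @param path CSV path.
#' @return `path` invisibly (write); the data.frame (read).
#' @export
write_diurnal_table <- function(table, path) {
  utils::write.csv(format(table, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_diurnal_table
#' @export
read_diurnal_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
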