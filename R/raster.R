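#' LST raster container
#'
#' Bundles one thermal overpass: per-pixel land-surface temperature (K),
#' per-pixel broadband emissivity, a validity mask, the grid cell size and
#' acquisition metadata. Matrices are row-major north-up: row 1 is the
#' northern edge.
#'
#' @param lst numeric matrix of LST values (K).
#' @param emissivity numeric matrix, same shape, values in (0, 1].
#' @param valid logical matrix, TRUE where the pixel carries data. Defaults
#'   to pixels where `lst` is finite.
#' @param cellsize grid spacing in metres (default 70, the nominal thermal
#'   footprint).
#' @param time overpass local time, decimal hours.
#' @param date acquisition date (anything printable; not interpreted).
#' @return An object of class `lst_raster`.
#' @export
lst_raster <- function(lst, emissivity, valid = NULL, cellsize = 70,
                       time = NA_real_, date = NA) {
  stopifnot(is.matrix(lst), is.matrix(emissivity),
            all(dim(lst) == dim(emissivity)))
  if (is.null(valid)) valid <- is.finite(lst)
  stopifnot(is.logical(valid), all(dim(valid) == dim(lst)))
  bad <- valid & (!is.finite(lst) | emissivity <= 0 | emissivity > 1 + 1e-9)
  if (any(bad)) stop("non-finite LST or emissivity outside (0,1] on valid pixels")
  structure(list(lst = lst, emissivity = emissivity, valid = valid,
                 cellsize = cellsize, time = time, date = date),
            class = "lst_raster")
}

#' @export
print.lst_raster <- function(x, ...) {
  cat(sprintf("<lst_raster> %d x %d pixels @ %g m, local time %s\n",
              nrow(x$lst), ncol(x$lst), x$cellsize,
              format(x$time)))
  v <- x$lst[x$valid]
  if (length(v)) cat(sprintf("  LST range %.2f-%.2f K, %d valid pixels\n",
                             min(v), max(v), length(v)))
  invisible(x)
}

#' @export
dim.lst_raster <- function(x) dim(x$lst)

#' Write a matrix as an ESRI ASCII grid
#'
#' Plain-text georeferenced raster format: six header lines then rows of
#' values, northern row first. Values are written with 17 significant
#' digits so that a write/read round trip is bit-exact for doubles.
#'
#' @param m numeric matrix (row 1 = north).
#' @param path output file path.
#' @param cellsize cell size in metres.
#' @param xll,yll coordinates of the lower-left corner (metres).
#' @param nodata value standing in for NA cells (default -9999).
#' @return `path`, invisibly.
#' @seealso [read_asc()]
#' @export
write_asc <- function(m, path, cellsize = 70, xll = 0, yll = 0,
                      nodata = -9999) {
  stopifnot(is.matrix(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.17g", xll),
    sprintf("yllcorner %.17g", yll),
    sprintf("cellsize %.17g", cellsize),
    sprintf("NODATA_value %.17g", nodata)), con)
  mm <- m
  mm[is.na(mm)] <- nodata
  for (i in seq_len(nrow(mm)))
    writeLines(paste(sprintf("%.17g", mm[i, ]), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_asc()] (or any conforming .asc).
#' @return A list with `values` (matrix, NA where nodata), `cellsize`,
#'   `xll`, `yll`.
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  nc <- as.integer(val[["ncols"]]); nr <- as.integer(val[["nrows"]])
  body <- scan(path, skip = 6L, quiet = TRUE)
  stopifnot(length(body) == nr * nc)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == val[["nodata_value"]]] <- NA_real_
  list(values = m, cellsize = val[["cellsize"]],
       xll = val[["xllcorner"]], yll = val[["yllcorner"]])
}

#' Write an 8-band fraction stack as ASCII grids plus a JSON manifest
#'
#' One .asc file per surface class plus `manifest.json` recording band
#' order and grid metadata.
#'
#' @param fractions rows x cols x 8 array (see [aggregate_fractions()]).
#' @param dir output directory (created if needed).
#' @param cellsize cell size in metres.
#' @return The manifest path, invisibly.
#' @export
write_fraction_stack <- function(fractions, dir, cellsize = 70) {
  stopifnot(length(dim(fractions)) == 3L, dim(fractions)[3] == 8L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cls <- ct_classes()
  files <- file.path(dir, paste0("fraction_", cls, ".asc"))
  for (k in seq_along(cls))
    write_asc(fractions[, , k], files[k], cellsize = cellsize)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(bands = cls, files = basename(files), cellsize = cellsize),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a fraction stack written by [write_fraction_stack()]
#'
#' @param dir directory containing the manifest and band files.
#' @return rows x cols x 8 array with class dimnames.
#' @export
read_fraction_stack <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  bands <- lapply(file.path(dir, manifest$files), function(f) read_asc(f)$values)
  out <- array(NA_real_, c(dim(bands[[1]]), length(bands)),
               dimnames = list(NULL, NULL, manifest$bands))
  for (k in seq_along(bands)) out[, , k] <- bands[[k]]
  out
}
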