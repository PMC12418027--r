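#' Environmental raster layer
#'
#' A single-band georeferenced grid in WGS84: a numeric matrix whose rows
#' run north to south and columns west to east, plus the geotransform
#' (lower-left corner and square cell size in degrees). This is the in-R
#' carrier for bioclim-style predictor layers; on disk layers travel as
#' ESRI ASCII grid (.asc), a plain-text single-band raster format.
#'
#' @param values Numeric matrix, row 1 = northernmost row.
#' @param xll,yll Lower-left corner of the grid (degrees).
#' @param cellsize Cell edge length in degrees (> 0).
#' @param name Variable name, e.g. "BIO1" or "ELEV".
#' @param nodata Sentinel written for missing cells (default -9999).
#' @return An object of class `env_layer`.
#' @export
env_layer <- function(values, xll, yll, cellsize, name = "layer",
                      nodata = -9999) {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (cellsize <= 0) stop("cellsize must be positive")
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, name = name, nodata = nodata,
                 crs = "EPSG:4326"),
            class = "env_layer")
}

#' @export
print.env_layer <- function(x, ...) {
  cat(sprintf("env_layer '%s': %d x %d cells, cellsize %g deg, origin (%g, %g)\n",
              x$name, nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  invisible(x)
}

#' Write / read an ESRI ASCII grid
#'
#' @param layer An [env_layer()].
#' @param path Output path (conventionally `.asc`).
#' @return `read_ascii_grid` returns an [env_layer()]; NA cells are the
#'   file's NODATA value.
#' @export
write_ascii_grid <- function(layer, path) {
  v <- layer$values
  v[is.na(v)] <- layer$nodata
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", layer$xll),
           sprintf("yllcorner %.10g", layer$yll),
           sprintf("cellsize %.10g", layer$cellsize),
           sprintf("NODATA_value %g", layer$nodata))
  body <- apply(v, 1, function(r) paste(formatC(r, format = "g", digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @param name Variable name to attach (default: file stem).
#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path, name = NULL) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- as.numeric(kv[, 2])
  names(vals) <- tolower(kv[, 1])
  body <- lines[-(1:6)]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"),
                             function(x) as.numeric(x)))
  m[m == vals[["nodata_value"]]] <- NA
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  env_layer(m, vals[["xllcorner"]], vals[["yllcorner"]],
            vals[["cellsize"]], name = name, nodata = vals[["nodata_value"]])
}

# Row/col of the cell containing each point; NA outside the extent.
cell_index <- function(layer, lon, lat) {
  nr <- nrow(layer$values); nc <- ncol(layer$values)
  col <- floor((lon - layer$xll) / layer$cellsize) + 1L
  # row 1 is the top (northern) row
  row <- nr - floor((lat - layer$yll) / layer$cellsize)
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = row, col = col)
}

#' Extract raster values at occurrence points
#'
#' Reads the value of the grid cell containing each point (no
#' interpolation), matching standard 30 arc-second bioclim sampling.
#' Records falling outside any layer's extent or hitting a missing cell are
#' dropped and listed in the report.
#'
#' @param layers List of [env_layer()] objects (all WGS84).
#' @param occ An [occurrence_set()].
#' @return A list: `env` (numeric matrix, one column per layer, one row per
#'   retained record), `occ` (the retained occurrence subset), `report`
#'   (indices and reasons of dropped records).
#' @export
extract_at_points <- function(layers, occ) {
  if (length(layers) == 0) stop("at least one layer required")
  if (!all(vapply(layers, function(l) identical(l$crs, "EPSG:4326"), TRUE)))
    stop("all layers must be WGS84 (EPSG:4326)")
  n <- nrow(occ)
  vals <- matrix(NA_real_, n, length(layers))
  colnames(vals) <- vapply(layers, `[[`, "", "name")
  for (j in seq_along(layers)) {
    l <- layers[[j]]
    ij <- cell_index(l, occ$lon, occ$lat)
    ok <- !is.na(ij$row)
    vals[ok, j] <- l$values[cbind(ij$row[ok], ij$col[ok])]
  }
  complete <- stats::complete.cases(vals)
  report <- data.frame(index = which(!complete),
                       species = occ$species[!complete],
                       lon = occ$lon[!complete], lat = occ$lat[!complete])
  kept <- occurrence_set(occ$species[complete], occ$lon[complete],
                         occ$lat[complete])
  list(env = vals[complete, , drop = FALSE], occ = kept,
       report = list(n_input = n, n_retained = sum(complete),
                     dropped = report))
}
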