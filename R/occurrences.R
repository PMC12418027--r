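#' Great-circle distance between points (haversine)
#'
#' Computes the haversine great-circle distance in kilometres between pairs
#' of WGS84 longitude/latitude coordinates. Inputs are recycled to a common
#' length, so one point against many is fine.
#'
#' @param lon1,lat1 Numeric vectors, decimal degrees of the first point(s).
#' @param lon2,lat2 Numeric vectors, decimal degrees of the second point(s).
#' @param radius_km Earth radius in km (default 6371).
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(0, 0, 0, 1)  # one degree of latitude, ~111.19 km
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2, radius_km = 6371) {
  check_lonlat(lon1, lat1)
  check_lonlat(lon2, lat2)
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  # clamp guards rounding at antipodes
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

check_lonlat <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("coordinates must be finite")
  if (any(lon < -180 | lon > 180))
    stop("longitude out of [-180, 180]")
  if (any(lat < -90 | lat > 90))
    stop("latitude out of [-90, 90]")
  invisible(TRUE)
}

#' Assemble an occurrence set
#'
#' An occurrence set is a data frame with columns `species`, `lon`, `lat`
#' (WGS84 / EPSG:4326 decimal degrees) plus an attribute recording the CRS.
#' Input row order is preserved throughout the pipeline.
#'
#' @param species Character vector of species labels (non-empty strings).
#' @param lon,lat Numeric coordinate vectors, decimal degrees.
#' @return A `data.frame` of class `occurrence_set`.
#' @export
occurrence_set <- function(species, lon, lat) {
  if (length(species) != length(lon) || length(lon) != length(lat))
    stop("species, lon and lat must have equal length")
  species <- as.character(species)
  if (length(species) && any(!nzchar(species) | is.na(species)))
    stop("species labels must be non-empty")
  if (length(lon)) check_lonlat(lon, lat)
  out <- data.frame(species = species, lon = as.numeric(lon),
                    lat = as.numeric(lat), stringsAsFactors = FALSE)
  attr(out, "crs") <- "EPSG:4326"
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Read / write occurrence CSV
#'
#' Plain CSV with columns `species,lon,lat`.
#'
#' @param path File path.
#' @return `read_occurrences` returns an [occurrence_set()].
#' @export
read_occurrences <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(d)))
    stop("occurrence CSV must have columns species, lon, lat")
  occurrence_set(d$species, d$lon, d$lat)
}

#' @param occ An [occurrence_set()].
#' @rdname read_occurrences
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ[, c("species", "lon", "lat")], path, row.names = FALSE)
  invisible(path)
}

#' Spatially thin occurrence records
#'
#' Removes duplicate-like records closer than `threshold_km` great-circle
#' distance, the standard guard against clustered collections biasing niche
#' density estimates. The scan is greedy and first-wins in input order: a
#' record is kept iff it is at least `threshold_km` from every previously
#' kept record of the comparison group. With `per_species = TRUE` (default)
#' records of different species never suppress each other.
#'
#' The operation is idempotent and order-stable: every retained pair within
#' a group is >= `threshold_km` apart, and every dropped record is within
#' `threshold_km` of some retained record of its group.
#'
#' @param occ An [occurrence_set()] or data frame with species/lon/lat.
#' @param threshold_km Minimum allowed pairwise distance in km (default 1).
#' @param per_species Thin within species only (default) or globally.
#' @param radius_km Earth radius for the haversine distance.
#' @return An [occurrence_set()] of retained records with attribute
#'   `report`: a list with `n_input`, `n_retained`, `dropped` (a data frame
#'   of dropped rows with the index of the retained record that excluded
#'   each).
#' @export
thin_occurrences <- function(occ, threshold_km = 1, per_species = TRUE,
                             radius_km = 6371) {
  if (threshold_km <= 0) stop("threshold_km must be positive")
  n <- nrow(occ)
  keep <- logical(n)
  excluded_by <- rep(NA_integer_, n)
  group <- if (per_species) occ$species else rep("all", n)
  for (g in unique(group)) {
    idx <- which(group == g)
    kept <- integer(0)
    for (i in idx) {
      if (length(kept)) {
        d <- haversine_km(occ$lon[kept], occ$lat[kept],
                          occ$lon[i], occ$lat[i], radius_km)
        j <- which(d < threshold_km)
        if (length(j)) {
          excluded_by[i] <- kept[j[1]]
          next
        }
      }
      keep[i] <- TRUE
      kept <- c(kept, i)
    }
  }
  out <- occurrence_set(occ$species[keep], occ$lon[keep], occ$lat[keep])
  dropped <- data.frame(index = which(!keep),
                        species = occ$species[!keep],
                        lon = occ$lon[!keep], lat = occ$lat[!keep],
                        excluded_by = excluded_by[!keep])
  attr(out, "report") <- list(n_input = n, n_retained = sum(keep),
                              threshold_km = threshold_km,
                              per_species = per_species, dropped = dropped)
  out
}
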