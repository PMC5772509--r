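#' Geographic adjustment terms for plant and faunal d13C
#'
#' Empirical regressions on modern C3 plants relate d13C to mean annual
#' precipitation (MAP), altitude and latitude. These terms move a measured
#' d13C value to a common reference environment (MAP = 1000 mm/yr,
#' altitude = 840 m, latitude = 50 degrees), so that widely dispersed fossil
#' records become comparable:
#' \itemize{
#'   \item `delta_map_term(map)` = `5.6 * (log10(map + 300) - log10(1300))`
#'   \item `delta_alt_term(alt)` = `0.00019 * (840 - alt)`
#'   \item `delta_lat_term(lat)` = `0.0124 * (|lat| - 50)`
#' }
#' All three vanish at the reference point; the MAP term is monotone
#' increasing in MAP and the latitude term depends only on |latitude|
#' (hemisphere-symmetric).
#'
#' @param map_mm modern mean annual precipitation, mm/yr (>= 0).
#' @param altitude_m site altitude, m (values below -430 m warn).
#' @param latitude site latitude, signed degrees, |lat| <= 90.
#' @return adjustment term in per mil; add it to the measured d13C.
#' @examples
#' delta_map_term(400)   # arid site: negative adjustment
#' delta_alt_term(0)     # sea level
#' delta_lat_term(70)    # high latitude
#' @name kohn_terms
NULL

#' @rdname kohn_terms
#' @export
delta_map_term <- function(map_mm) {
  if (any(!is.finite(map_mm)) || any(map_mm < 0))
    stop("'map_mm' must be finite and >= 0")
  5.6 * (log10(map_mm + 300) - log10(1300))
}

#' @rdname kohn_terms
#' @export
delta_alt_term <- function(altitude_m) {
  if (any(!is.finite(altitude_m))) stop("'altitude_m' must be finite")
  if (any(altitude_m < -430))
    warning("altitude below -430 m (lowest land surface)")
  0.00019 * (840 - altitude_m)
}

#' @rdname kohn_terms
#' @export
delta_lat_term <- function(latitude) {
  if (any(!is.finite(latitude)) || any(abs(latitude) > 90))
    stop("'latitude' must be within [-90, 90]")
  0.0124 * (abs(latitude) - 50)
}

#' Adjust d13C to the reference environment
#'
#' Computes the three geographic terms and returns the adjusted value
#' `d13c + d_map + d_alt + d_lat`. The adjustment is exactly invertible:
#' subtracting the same terms recovers the input.
#'
#' @param d13c measured d13C, per mil VPDB (vectorised).
#' @param map_mm,altitude_m,latitude site environment (vectorised, recycled).
#' @return data frame with columns `d13c_adj`, `d_map`, `d_alt`, `d_lat`,
#'   `d_total`.
#' @examples
#' geo_adjust(-21, map_mm = 400, altitude_m = 0, latitude = 70)
#' @export
geo_adjust <- function(d13c, map_mm, altitude_m, latitude) {
  d_map <- delta_map_term(map_mm)
  d_alt <- delta_alt_term(altitude_m)
  d_lat <- delta_lat_term(latitude)
  d_total <- d_map + d_alt + d_lat
  data.frame(d13c_adj = d13c + d_total,
             d_map = d_map, d_alt = d_alt, d_lat = d_lat, d_total = d_total)
}

#' Adjust a table of proxy records in place
#'
#' Convenience wrapper applying [geo_adjust()] to a record table, appending
#' the adjustment columns. Records must carry `d13c`, `map_mm`, `altitude_m`
#' and `lat` columns (site values may come from [grid_lookup()] or be
#' supplied directly).
#'
#' @param records data frame of proxy records.
#' @return `records` with `d13c_adj`, `d_map`, `d_alt`, `d_lat`, `d_total`
#'   columns appended.
#' @export
adjust_records <- function(records) {
  stopifnot_cols(records, c("d13c", "map_mm", "altitude_m", "lat"), "records")
  adj <- geo_adjust(records$d13c, records$map_mm, records$altitude_m,
                    records$lat)
  cbind(records[setdiff(names(records), names(adj))], adj)
}

#' In-memory gridded climatology / elevation field
#'
#' A minimal regular lat/lon grid supporting nearest-cell lookup, standing
#' in for a digital elevation model or precipitation climatology. Values
#' are stored as a matrix indexed `[lat, lon]`; cells may be `NA`
#' (missing data, e.g. ocean).
#'
#' @param lat,lon ascending vectors of cell-centre coordinates, degrees.
#' @param values numeric matrix, `length(lat)` x `length(lon)`.
#' @return an object of class `"climate_grid"`.
#' @seealso [grid_lookup()], [read_climate_grid()]
#' @export
climate_grid <- function(lat, lon, values) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(lat), ncol(values) == length(lon))
  if (any(diff(lat) <= 0) || any(diff(lon) <= 0))
    stop("'lat' and 'lon' must be strictly ascending")
  structure(list(lat = lat, lon = lon, values = values),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("<climate_grid> %d x %d cells, lat [%.2f, %.2f], lon [%.2f, %.2f]\n",
              length(x$lat), length(x$lon), min(x$lat), max(x$lat),
              min(x$lon), max(x$lon)))
  invisible(x)
}

#' Nearest-cell value at site coordinates
#'
#' Looks up the grid cell whose centre is nearest to each site (no
#' interpolation: nearest-cell lookup is reproducible and matches the
#' resolution of the source grids). Sites outside the grid bounds (beyond
#' half a cell from the outermost centres) or hitting a missing-data cell
#' raise an error naming the offending site index.
#'
#' @param grid a [climate_grid()].
#' @param lat,lon site coordinates, degrees (vectorised).
#' @return numeric vector of grid values.
#' @export
grid_lookup <- function(grid, lat, lon) {
  stopifnot(inherits(grid, "climate_grid"))
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  half_la <- stats::median(diff(grid$lat)) / 2
  half_lo <- stats::median(diff(grid$lon)) / 2
  bad <- lat < min(grid$lat) - half_la | lat > max(grid$lat) + half_la |
         lon < min(grid$lon) - half_lo | lon > max(grid$lon) + half_lo
  if (any(bad))
    stop("site(s) outside grid bounds: ", paste(which(bad), collapse = ", "))
  ii <- vapply(lat, function(z) which.min(abs(grid$lat - z)), integer(1))
  jj <- vapply(lon, function(z) which.min(abs(grid$lon - z)), integer(1))
  v <- grid$values[cbind(ii, jj)]
  if (anyNA(v))
    stop("missing-data cell at site(s): ",
         paste(which(is.na(v)), collapse = ", "))
  v
}

#' Read a gridded field from long-format CSV
#'
#' Reads a plain-text grid with columns `lat, lon, value` (one row per
#' cell) into a [climate_grid()].
#'
#' @param path CSV file path.
#' @return a [climate_grid()].
#' @export
read_climate_grid <- function(path) {
  df <- read.csv(path)
  stopifnot_cols(df, c("lat", "lon", "value"), "grid file")
  la <- sort(unique(df$lat)); lo <- sort(unique(df$lon))
  m <- matrix(NA_real_, length(la), length(lo))
  m[cbind(match(df$lat, la), match(df$lon, lo))] <- df$value
  climate_grid(la, lo, m)
}
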