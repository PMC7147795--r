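#' Regular latitude/longitude grid
#'
#' The coordinate home of every gridded field in the package: ascending,
#' uniformly spaced latitudes and longitudes on a spherical Earth.
#'
#' @param lats Numeric vector of latitudes in degrees north, strictly
#'   ascending, uniformly spaced (within 1e-9 degrees), length >= 3.
#' @param lons Numeric vector of longitudes in degrees east, strictly
#'   monotone, uniformly spaced, length >= 3. Either the [0, 360) or the
#'   [-180, 180) convention may be used; the grid records whatever it is
#'   given.
#' @param radius Earth radius in metres (default 6.371e6).
#' @return An object of class `geo_grid`: a list with elements `lats`,
#'   `lons`, `radius`, `dlat`, `dlon` (spacings in degrees).
#' @examples
#' g <- geo_grid(lats = seq(10, 15, by = 0.25), lons = seq(65, 70, by = 0.25))
#' g
#' @export
geo_grid <- function(lats, lons, radius = 6.371e6) {
  stopifnot(is.numeric(lats), is.numeric(lons), length(radius) == 1L,
            is.finite(radius), radius > 0)
  if (length(lats) < 3L || length(lons) < 3L)
    stop("geo_grid needs at least 3 points per axis (centered differences)")
  dlat <- diff(lats)
  dlon <- diff(lons)
  if (any(dlat <= 0)) stop("latitudes must be strictly ascending")
  if (max(abs(dlat - dlat[1])) > 1e-9 || max(abs(dlon - dlon[1])) > 1e-9)
    stop("grid spacing must be uniform within 1e-9 degrees on each axis")
  if (any(abs(lats) > 90)) stop("latitudes must lie in [-90, 90]")
  structure(
    list(lats = as.numeric(lats), lons = as.numeric(lons),
         radius = radius, dlat = dlat[1], dlon = dlon[1]),
    class = "geo_grid"
  )
}

#' @export
print.geo_grid <- function(x, ...) {
  cat(sprintf("<geo_grid> %d lats [%g, %g] x %d lons [%g, %g], spacing %g x %g deg\n",
              length(x$lats), min(x$lats), max(x$lats),
              length(x$lons), min(x$lons), max(x$lons), x$dlat, x$dlon))
  invisible(x)
}

#' Rectangular geographic box
#'
#' Study boxes are addressed by their latitude/longitude bounds, e.g. the
#' 11-14 degN, 67-70 degE box at the centre of the bloom analysis. Bounds are
#' inclusive on all edges; a grid pixel belongs to the box if its centre lies
#' inside.
#'
#' @param lat_min,lat_max,lon_min,lon_max Box edges in degrees.
#' @return An object of class `box_region`.
#' @examples
#' box_region(11, 14, 67, 70)
#' @export
box_region <- function(lat_min, lat_max, lon_min, lon_max) {
  stopifnot(is.numeric(lat_min), is.numeric(lat_max),
            is.numeric(lon_min), is.numeric(lon_max))
  if (!(lat_min < lat_max)) stop("lat_min must be < lat_max")
  if (!(lon_min < lon_max)) stop("lon_min must be < lon_max")
  structure(list(lat_min = lat_min, lat_max = lat_max,
                 lon_min = lon_min, lon_max = lon_max),
            class = "box_region")
}

#' @export
print.box_region <- function(x, ...) {
  cat(sprintf("<box_region> %g-%g degN, %g-%g degE\n",
              x$lat_min, x$lat_max, x$lon_min, x$lon_max))
  invisible(x)
}

# logical index vectors of grid rows/cols whose pixel centres fall in the box
box_index <- function(grid, box) {
  ilat <- grid$lats >= box$lat_min & grid$lats <= box$lat_max
  ilon <- grid$lons >= box$lon_min & grid$lons <= box$lon_max
  if (!any(ilat) || !any(ilon))
    stop("box does not overlap the grid")
  list(ilat = ilat, ilon = ilon)
}

#' Coriolis parameter
#'
#' f = 2 * Omega * sin(phi), with Omega the Earth rotation rate.
#'
#' @param lat Latitude(s), degrees north.
#' @param omega Rotation rate, s^-1 (default 7.2921e-5).
#' @return f in s^-1, same shape as `lat`.
#' @export
coriolis <- function(lat, omega = 7.2921e-5) {
  2 * omega * sin(lat * pi / 180)
}

deg2rad <- function(x) x * pi / 180

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Great-circle (haversine) distance
#'
#' Distance on a sphere of radius `radius` between points given in degrees.
#' Vectorised over both points.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in degrees.
#' @param radius Sphere radius in metres (default 6.371e6, the value used
#'   for all track and grid geometry in this package).
#' @return Distance in metres.
#' @export
haversine <- function(lat1, lon1, lat2, lon2, radius = 6.371e6) {
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dphi <- p2 - p1
  dlam <- deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * radius * asin(pmin(1, sqrt(a)))
}

# run an expression under a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialise a seed to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
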