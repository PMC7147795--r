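# Plain-text gridded-field dialect
#
# Long-format CSV with '#'-prefixed metadata header lines, carrying the same
# information as the CF-style convention (dimensions time/lat/lon, variable
# name, units, fill as NA, ascending lat, recorded lon convention). Chosen
# over NetCDF so the package has no binary dependencies.

write_meta <- function(con, kv) {
  for (k in names(kv)) cat(sprintf("# %s: %s\n", k, kv[[k]]), file = con)
}

read_meta <- function(lines) {
  ml <- lines[startsWith(lines, "#")]
  kv <- list()
  for (l in ml) {
    m <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  kv
}

fmt_time <- function(times) {
  if (inherits(times, "POSIXct")) format(times, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  else if (inherits(times, "Date")) format(times)
  else as.character(times)
}

parse_time <- function(x, type) {
  switch(type,
         POSIXct = as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
         Date = as.Date(x),
         as.numeric(x))
}

time_type <- function(times) {
  if (inherits(times, "POSIXct")) "POSIXct"
  else if (inherits(times, "Date")) "Date"
  else "numeric"
}

#' Write a gridded series to plain text
#'
#' Serialises a [scalar_series()] or [vector_series()] as long-format CSV
#' (`time,lat,lon,value` or `time,lat,lon,u,v`) preceded by `# key: value`
#' metadata lines (variable name, units, fill semantics, longitude
#' convention, Earth radius). Masked pixels are written as `NA`.
#'
#' @param x A [scalar_series()] or [vector_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_field_series()]
#' @export
write_field_series <- function(x, path) {
  stopifnot(inherits(x, "scalar_series") || inherits(x, "vector_series"))
  con <- file(path, "w")
  on.exit(close(con))
  lonconv <- if (any(x$grid$lons > 180)) "[0,360)" else "[-180,180)"
  write_meta(con, list(format = "tcbloom-grid-1",
                       kind = class(x)[1],
                       varname = x$varname, units = x$units,
                       fill = "NA", lat_order = "ascending",
                       lon_convention = lonconv,
                       earth_radius_m = format(x$grid$radius),
                       time_type = time_type(x$times)))
  nlat <- length(x$grid$lats); nlon <- length(x$grid$lons)
  tms <- rep(fmt_time(x$times), each = nlat * nlon)
  latv <- rep(rep(x$grid$lats, times = nlon), times = length(x$times))
  lonv <- rep(rep(x$grid$lons, each = nlat), times = length(x$times))
  if (inherits(x, "scalar_series")) {
    cat("time,lat,lon,value\n", file = con)
    cat(sprintf("%s,%.10g,%.10g,%s", tms, latv, lonv,
                ifelse(is.na(x$data), "NA", sprintf("%.10g", x$data))),
        sep = "\n", file = con)
  } else {
    cat("time,lat,lon,u,v\n", file = con)
    cat(sprintf("%s,%.10g,%.10g,%s,%s", tms, latv, lonv,
                ifelse(is.na(x$u), "NA", sprintf("%.10g", x$u)),
                ifelse(is.na(x$v), "NA", sprintf("%.10g", x$v))),
        sep = "\n", file = con)
  }
  invisible(path)
}

#' Read a gridded series from plain text
#'
#' Inverse of [write_field_series()]: reconstructs the [geo_grid()] from the
#' unique latitudes/longitudes and returns a [scalar_series()] or
#' [vector_series()] according to the file's `kind` metadata.
#'
#' @param path Path written by [write_field_series()].
#' @return A [scalar_series()] or [vector_series()].
#' @export
read_field_series <- function(path) {
  lines <- readLines(path)
  kv <- read_meta(lines)
  if (!identical(kv$format, "tcbloom-grid-1"))
    stop("not a tcbloom-grid-1 file: ", path)
  df <- utils::read.csv(textConnection(lines[!startsWith(lines, "#")]))
  lats <- sort(unique(df$lat))
  lons <- sort(unique(df$lon))
  radius <- as.numeric(kv$earth_radius_m %||% 6.371e6)
  grid <- geo_grid(lats, lons, radius)
  tstr <- unique(df$time)
  times <- parse_time(tstr, kv$time_type %||% "numeric")
  nlat <- length(lats); nlon <- length(lons); nt <- length(tstr)
  ord <- order(match(df$time, tstr), match(df$lon, lons), match(df$lat, lats))
  if (nrow(df) != nlat * nlon * nt) stop("incomplete grid in ", path)
  if (identical(kv$kind, "vector_series")) {
    vector_series(grid,
                  array(df$u[ord], c(nlat, nlon, nt)),
                  array(df$v[ord], c(nlat, nlon, nt)),
                  times, varname = kv$varname %||% "uv",
                  units = kv$units %||% "")
  } else {
    scalar_series(grid, array(df$value[ord], c(nlat, nlon, nt)),
                  times, varname = kv$varname %||% "value",
                  units = kv$units %||% "")
  }
}

#' Write a hydrographic profile as 3-column text
#'
#' Whitespace-separated columns `depth_m temp_C sal_psu` with a header line,
#' the standard minimal exchange format for float profiles.
#'
#' @param profile A [hydro_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "hydro_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(profile$station))
    write_meta(con, list(lat = profile$station$lat, lon = profile$station$lon,
                         time = profile$station$time))
  cat("depth_m temp_C sal_psu\n", file = con)
  cat(sprintf("%.6g %.10g %.10g", profile$depth, profile$temp, profile$sal),
      sep = "\n", file = con)
  invisible(path)
}

#' Read a 3-column profile text file
#'
#' @param path Path to a file with columns `depth_m temp_C sal_psu`
#'   (whitespace- or comma-separated; `#` comments and an optional header
#'   line are skipped).
#' @return A [hydro_profile()].
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  kv <- read_meta(lines)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (grepl("[A-Za-z]", lines[1])) lines <- lines[-1]
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  m <- t(vapply(parts, function(p) as.numeric(p[1:3]), numeric(3)))
  if (anyNA(m)) stop("unparsable profile rows in ", path)
  station <- if (length(kv)) list(lat = as.numeric(kv$lat),
                                  lon = as.numeric(kv$lon),
                                  time = kv$time) else NULL
  hydro_profile(m[, 1], m[, 2], m[, 3], station = station)
}
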