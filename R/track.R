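#' Construct a cyclone best track
#'
#' A best track is an ordered set of 6-hourly fixes: time, position, and
#' maximum sustained wind (MSW). Translation speed at each fix is computed on
#' construction as the great-circle distance from the previous fix divided by
#' the elapsed time; the first fix has no speed (`NA`), matching best-track
#' table convention.
#'
#' @param time `POSIXct` (UTC) fix times, strictly increasing.
#' @param lat,lon Fix positions, degrees.
#' @param msw Maximum sustained wind at each fix, m s^-1, non-negative.
#' @return An object of class `tc_track`: a data.frame with columns `time`,
#'   `lat`, `lon`, `msw`, `ts` (translation speed, m s^-1) and `category`
#'   (from [classify_intensity()]).
#' @seealso [parse_track()], [translation_speed()]
#' @export
tc_track <- function(time, lat, lon, msw) {
  stopifnot(inherits(time, "POSIXct"))
  n <- length(time)
  if (n < 2L) stop("a track needs at least 2 fixes (no speed computable from 1)")
  if (length(lat) != n || length(lon) != n || length(msw) != n)
    stop("time, lat, lon, msw must have equal length")
  if (anyDuplicated(time)) stop("duplicate timestamps in track")
  if (is.unsorted(time, strictly = TRUE)) stop("track times must be strictly increasing")
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
  if (any(msw < 0)) stop("negative maximum sustained wind")
  out <- data.frame(time = time, lat = as.numeric(lat), lon = as.numeric(lon),
                    msw = as.numeric(msw))
  out$ts <- translation_speed_(out)
  out$category <- classify_intensity(out$msw)
  class(out) <- c("tc_track", "data.frame")
  out
}

# speeds at arrival fixes; NA at the first
translation_speed_ <- function(df) {
  n <- nrow(df)
  dt <- as.numeric(difftime(df$time[-1], df$time[-n], units = "secs"))
  if (any(dt <= 0)) stop("zero or negative elapsed time between fixes")
  d <- haversine(df$lat[-n], df$lon[-n], df$lat[-1], df$lon[-1], radius = 6371e3)
  c(NA_real_, d / dt)
}

#' Translation speed along a track
#'
#' Great-circle (haversine, R = 6371 km) distance between consecutive fixes
#' divided by the elapsed seconds, reported at the arrival fix. The first fix
#' has no defined speed and is `NA`.
#'
#' @param track A [tc_track()].
#' @return Numeric vector of speeds in m s^-1, one per fix.
#' @export
translation_speed <- function(track) {
  stopifnot(inherits(track, "tc_track"))
  translation_speed_(track)
}

# intensity bands by maximum sustained wind, half-open, gaps closed upward
.intensity_breaks <- c(0, 10.8, 17.2, 24.5, 32.7, 42, 52, Inf)
.intensity_labels <- c("below_depression", "tropical_depression",
                       "tropical_storm", "severe_tropical_storm",
                       "typhoon", "severe_typhoon", "super_severe_typhoon")

#' Classify cyclone intensity from maximum sustained wind
#'
#' Categories follow the wind-speed bands used for north Indian Ocean
#' systems: tropical depression 10.8-17.1, tropical storm 17.2-24.4, severe
#' tropical storm 24.5-32.6, typhoon 32.7-41, severe typhoon 42-51, and
#' super-severe typhoon above 52 m s^-1. The printed bands leave (41, 42) and
#' (51, 52) unassigned; for totality each band is implemented half-open with
#' the gap closed upward, i.e. `[32.7, 42)`, `[42, 52)`, `[52, Inf)`. Winds
#' below 10.8 m s^-1 are labelled `below_depression`.
#'
#' @param msw Maximum sustained wind, m s^-1, non-negative. Vectorised.
#' @return An ordered factor with levels from `below_depression` up to
#'   `super_severe_typhoon`.
#' @examples
#' classify_intensity(c(5, 12.5, 35, 42.5, 60))
#' @export
classify_intensity <- function(msw) {
  if (any(!is.finite(msw)) || any(msw < 0))
    stop("msw must be finite and non-negative")
  cut(msw, breaks = .intensity_breaks, labels = .intensity_labels,
      right = FALSE, ordered_result = TRUE)
}

#' Parse a best-track CSV
#'
#' Reads a 6-hourly best-track table with columns `lat`, `lon`, `time`
#' (format `MM/DD/HH`, UTC) and `msw` (m s^-1). The year is not part of the
#' table format and must be supplied; month rollovers within a track (e.g.
#' November into December) are handled.
#'
#' @param path Path to the CSV file, or a character vector of CSV lines.
#' @param year Calendar year of the first fix.
#' @return A [tc_track()].
#' @examples
#' txt <- c("lat,lon,time,msw",
#'          "5.9,80.8,11/29/06,12.5",
#'          "6.2,79.7,11/29/12,12.5")
#' parse_track(txt, year = 2017)
#' @export
parse_track <- function(path, year) {
  stopifnot(is.numeric(year), length(year) == 1L)
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L) stop("track file needs a header and at least 2 rows")
  header <- tolower(strsplit(lines[1], ",")[[1]])
  need <- c("lat", "lon", "time", "msw")
  if (!all(need %in% trimws(header)))
    stop("track header must contain columns: lat, lon, time, msw")
  idx <- match(need, trimws(header))
  rows <- lines[-1]
  if (length(rows) < 2L) stop("a track needs at least 2 fixes")
  parse_row <- function(i) {
    parts <- trimws(strsplit(rows[i], ",")[[1]])
    if (length(parts) < length(header))
      stop(sprintf("malformed track row at line %d: '%s'", i + 1L, rows[i]))
    lat <- suppressWarnings(as.numeric(parts[idx[1]]))
    lon <- suppressWarnings(as.numeric(parts[idx[2]]))
    msw <- suppressWarnings(as.numeric(parts[idx[4]]))
    tm <- strsplit(parts[idx[3]], "/")[[1]]
    if (length(tm) != 3L || is.na(lat) || is.na(lon) || is.na(msw) ||
        anyNA(suppressWarnings(as.integer(tm))))
      stop(sprintf("malformed track row at line %d: '%s'", i + 1L, rows[i]))
    list(lat = lat, lon = lon, msw = msw,
         mon = as.integer(tm[1]), day = as.integer(tm[2]), hr = as.integer(tm[3]))
  }
  parsed <- lapply(seq_along(rows), parse_row)
  mon <- vapply(parsed, `[[`, integer(1), "mon")
  # year rollover: a month smaller than its predecessor implies January next year
  yr <- year + cumsum(c(0L, diff(mon) < 0))
  time <- as.POSIXct(sprintf("%04d-%02d-%02d %02d:00:00", yr, mon,
                             vapply(parsed, `[[`, integer(1), "day"),
                             vapply(parsed, `[[`, integer(1), "hr")),
                     tz = "UTC")
  if (anyNA(time)) stop("unparsable time in track")
  tc_track(time = time,
           lat = vapply(parsed, `[[`, numeric(1), "lat"),
           lon = vapply(parsed, `[[`, numeric(1), "lon"),
           msw = vapply(parsed, `[[`, numeric(1), "msw"))
}

#' Write a track back to CSV
#'
#' Inverse of [parse_track()]: emits `lat,lon,time,msw` rows in `MM/DD/HH`
#' time format so that parse -> write -> parse round-trips all fields.
#'
#' @param track A [tc_track()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "tc_track"))
  tm <- format(track$time, "%m/%d/%H", tz = "UTC")
  lines <- c("lat,lon,time,msw",
             sprintf("%g,%g,%s,%g", track$lat, track$lon, tm, track$msw))
  writeLines(lines, path)
  invisible(path)
}

#' Interpolate the cyclone centre between fixes
#'
#' Great-circle (spherical linear) interpolation of the storm centre,
#' linear in time between the bracketing 6-hourly fixes.
#'
#' @param track A [tc_track()].
#' @param times `POSIXct` times, each within the track's time span.
#' @return A data.frame with columns `time`, `lat`, `lon`.
#' @export
track_position <- function(track, times) {
  stopifnot(inherits(track, "tc_track"), inherits(times, "POSIXct"))
  t0 <- as.numeric(track$time)
  tq <- as.numeric(times)
  if (any(tq < t0[1] | tq > t0[length(t0)]))
    stop("requested time outside the track's time span")
  i <- findInterval(tq, t0, rightmost.closed = TRUE)
  w <- (tq - t0[i]) / (t0[i + 1L] - t0[i])
  # slerp between the unit position vectors of the bracketing fixes
  to_xyz <- function(lat, lon) {
    la <- deg2rad(lat); lo <- deg2rad(lon)
    cbind(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
  }
  a <- to_xyz(track$lat[i], track$lon[i])
  b <- to_xyz(track$lat[i + 1L], track$lon[i + 1L])
  dotab <- pmin(1, pmax(-1, rowSums(a * b)))
  ang <- acos(dotab)
  s <- sin(ang)
  wa <- ifelse(s < 1e-12, 1 - w, sin((1 - w) * ang) / s)
  wb <- ifelse(s < 1e-12, w, sin(w * ang) / s)
  p <- a * wa + b * wb
  p <- p / sqrt(rowSums(p^2))
  data.frame(time = times,
             lat = asin(p[, 3]) * 180 / pi,
             lon = atan2(p[, 2], p[, 1]) * 180 / pi)
}
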