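#' Parametric vortex wind parameters
#'
#' A Rankine-type tangential wind profile with a configurable outer decay:
#' v(r) = vmax * r / rmax inside the radius of maximum wind, and
#' vmax * (rmax / r)^decay_exponent outside. Simpler than a Holland profile,
#' analytically invertible, and any smooth cyclonic vortex exercises the
#' same curl/Ekman-pumping code paths.
#'
#' @param vmax Peak tangential wind speed, m s^-1 (>= 0).
#' @param rmax Radius of maximum wind, km (> 0).
#' @param decay_exponent Dimensionless outer-decay power (> 0, default 0.5).
#' @param background_wind Uniform ambient wind `c(u, v)`, m s^-1.
#' @return An object of class `vortex_params`.
#' @export
vortex_params <- function(vmax, rmax, decay_exponent = 0.5,
                          background_wind = c(0, 0)) {
  stopifnot(vmax >= 0, rmax > 0, decay_exponent > 0,
            length(background_wind) == 2L, all(is.finite(background_wind)))
  structure(list(vmax = vmax, rmax = rmax, decay_exponent = decay_exponent,
                 background_wind = as.numeric(background_wind)),
            class = "vortex_params")
}

#' Gaussian cyclonic eddy specification
#'
#' @param center `c(lat, lon)` of the eddy centre, degrees.
#' @param amplitude SSH anomaly at the centre, metres; negative for a
#'   cyclonic (NH) eddy.
#' @param radius e-folding scale of the Gaussian SSH anomaly, km (> 0).
#' @return An object of class `eddy_spec`.
#' @export
eddy_spec <- function(center, amplitude, radius) {
  stopifnot(length(center) == 2L, all(is.finite(center)), radius > 0,
            is.finite(amplitude))
  structure(list(center = as.numeric(center), amplitude = amplitude,
                 radius = radius), class = "eddy_spec")
}

#' Tanh-thermocline stratification parameters
#'
#' @param sst Surface temperature, degC.
#' @param deep_t Abyssal temperature, degC (`sst >= deep_t`).
#' @param thermocline_depth Depth of the maximum vertical gradient, m (> 0).
#' @param thermocline_width Half-width of the tanh transition, m (> 0).
#' @param sss,deep_s Surface and deep salinity, psu.
#' @return An object of class `stratification_params`.
#' @export
stratification_params <- function(sst = 29, deep_t = 12,
                                  thermocline_depth = 46.2,
                                  thermocline_width = 10,
                                  sss = 36.0, deep_s = 35.2) {
  stopifnot(thermocline_depth > 0, thermocline_width > 0, sst >= deep_t)
  structure(list(sst = sst, deep_t = deep_t,
                 thermocline_depth = thermocline_depth,
                 thermocline_width = thermocline_width,
                 sss = sss, deep_s = deep_s),
            class = "stratification_params")
}

#' Lagged bloom scenario
#'
#' Parameterises the structure the downstream analysis assumes: every pixel's
#' chlorophyll-a rises from `baseline_chl` to `peak_chl` exactly `lag_days`
#' days after the cyclone's closest approach to that pixel, then relaxes
#' exponentially (e-folding `efold_days`). Pixels are independently
#' cloud-masked with probability `cloud_fraction` each day.
#'
#' @param baseline_chl Pre-storm concentration, mg m^-3 (> 0).
#' @param peak_chl Bloom peak, mg m^-3 (>= `baseline_chl`).
#' @param lag_days Whole days between local closest approach and the local
#'   chlorophyll peak (>= 0; default 4).
#' @param cloud_fraction Per-pixel-day masking probability in [0, 1).
#' @param seed RNG seed for the cloud mask (integer).
#' @param efold_days Post-peak relaxation e-folding time, days (default 3).
#' @return An object of class `bloom_scenario`.
#' @export
bloom_scenario <- function(baseline_chl = 0.26, peak_chl = 4.68,
                           lag_days = 4, cloud_fraction = 0.3, seed = 1,
                           efold_days = 3) {
  stopifnot(baseline_chl > 0, peak_chl >= baseline_chl, lag_days >= 0,
            cloud_fraction >= 0, cloud_fraction < 1, efold_days > 0)
  structure(list(baseline_chl = baseline_chl, peak_chl = peak_chl,
                 lag_days = as.integer(lag_days),
                 cloud_fraction = cloud_fraction,
                 seed = as.integer(seed), efold_days = efold_days),
            class = "bloom_scenario")
}

#' Wind field of a translating parametric cyclone
#'
#' Evaluates the Rankine vortex of `params`, rotating counterclockwise
#' (Northern-Hemisphere cyclonic) about the storm centre interpolated along
#' `track`, plus the uniform background wind. Nothing is masked.
#'
#' @param track A [tc_track()]. Every requested time must lie within the
#'   track's time span.
#' @param params A [vortex_params()].
#' @param grid A [geo_grid()].
#' @param times `POSIXct` times at which to evaluate the field.
#' @return A [vector_series()] of 10-m winds, m s^-1.
#' @export
gen_vortex_wind <- function(track, params, grid, times) {
  stopifnot(inherits(params, "vortex_params"), inherits(grid, "geo_grid"))
  centers <- track_position(track, times) # errors if outside span
  nlat <- length(grid$lats); nlon <- length(grid$lons); nt <- length(times)
  u <- array(0, c(nlat, nlon, nt)); v <- array(0, c(nlat, nlon, nt))
  latm <- matrix(grid$lats, nlat, nlon)
  lonm <- matrix(grid$lons, nlat, nlon, byrow = TRUE)
  for (k in seq_len(nt)) {
    uv <- vortex_wind_at(latm, lonm, centers$lat[k], centers$lon[k], params,
                         grid$radius)
    u[, , k] <- uv$u
    v[, , k] <- uv$v
  }
  vector_series(grid, u, v, times, varname = "wind10m", units = "m s-1")
}

# Rankine tangential speed, r and rmax in metres
rankine_speed <- function(r, vmax, rmax_m, decay) {
  ifelse(r <= rmax_m, vmax * r / rmax_m, vmax * (rmax_m / r)^decay)
}

# vortex wind components on a local tangent plane about the storm centre
vortex_wind_at <- function(lat, lon, clat, clon, params, radius) {
  dx <- radius * cos(deg2rad(clat)) * deg2rad(lon - clon)
  dy <- radius * deg2rad(lat - clat)
  r <- sqrt(dx^2 + dy^2)
  vt <- rankine_speed(r, params$vmax, params$rmax * 1e3, params$decay_exponent)
  frac <- ifelse(r > 0, vt / r, 0) # counterclockwise: v = vt * (-dy, dx)/r
  list(u = -frac * dy + params$background_wind[1],
       v = frac * dx + params$background_wind[2])
}

#' Gaussian eddy SSH field and its geostrophic currents
#'
#' SSH is the superposition of Gaussian anomalies,
#' eta = sum_i A_i exp(-d_i^2 / (2 radius_i^2)), with d the local tangent-
#' plane distance to each eddy centre. Surface currents are geostrophic:
#' u = -(g/f) d(eta)/dy, v = (g/f) d(eta)/dx, with the gradient taken
#' analytically so that superposition is exact. A negative-amplitude eddy
#' yields counterclockwise (cyclonic, NH) circulation and positive relative
#' vorticity at its centre. Geostrophy is undefined at the equator, so grids
#' touching |lat| < 2 degrees are rejected.
#'
#' @param eddies A list of [eddy_spec()] (possibly empty).
#' @param grid A [geo_grid()] with all |latitudes| >= 2 degrees.
#' @param times Optional time stamps; the (steady) field is replicated.
#' @return A list with `ssh` (a [scalar_series()], m) and `currents`
#'   (a [current_field()], m s^-1).
#' @export
gen_eddy_ssh_currents <- function(eddies, grid, times = 1) {
  stopifnot(inherits(grid, "geo_grid"))
  if (any(abs(grid$lats) < 2))
    stop("geostrophic currents undefined near the equator: need |lat| >= 2 deg")
  nlat <- length(grid$lats); nlon <- length(grid$lons)
  latm <- matrix(grid$lats, nlat, nlon)
  lonm <- matrix(grid$lons, nlat, nlon, byrow = TRUE)
  g <- 9.81
  f <- matrix(coriolis(grid$lats), nlat, nlon)
  ssh <- matrix(0, nlat, nlon)
  detadx <- matrix(0, nlat, nlon)
  detady <- matrix(0, nlat, nlon)
  for (e in eddies) {
    stopifnot(inherits(e, "eddy_spec"))
    r2 <- (e$radius * 1e3)^2
    dx <- grid$radius * cos(latm * pi / 180) * deg2rad(lonm - e$center[2])
    dy <- grid$radius * deg2rad(latm - e$center[1])
    eta <- e$amplitude * exp(-(dx^2 + dy^2) / (2 * r2))
    ssh <- ssh + eta
    detadx <- detadx - eta * dx / r2
    detady <- detady - eta * dy / r2
  }
  u <- -(g / f) * detady
  v <- (g / f) * detadx
  nt <- length(times)
  rep3 <- function(m) array(rep(m, nt), c(nlat, nlon, nt))
  list(ssh = scalar_series(grid, rep3(ssh), times, "ssh", "m"),
       currents = current_field(grid,
                                array(rep(u, nt), c(nlat, nlon, 1L, nt)),
                                array(rep(v, nt), c(nlat, nlon, 1L, nt)),
                                depths = 0, times = times))
}

#' Synthetic tanh-thermocline profile
#'
#' T(z) interpolates between `sst` at the surface and `deep_t` at depth
#' through a tanh transition centred on `thermocline_depth` with half-width
#' `thermocline_width`, normalised so T(0) = sst exactly; salinity follows
#' the same shape between `sss` and `deep_s`. The maximum vertical gradient
#' (hence the maximum buoyancy frequency under the linear equation of state)
#' sits at `thermocline_depth` by construction.
#'
#' @param params A [stratification_params()].
#' @param depths Strictly increasing depths, m positive down.
#' @param station Optional station metadata (see [hydro_profile()]).
#' @return A [hydro_profile()].
#' @export
gen_profile <- function(params, depths, station = NULL) {
  stopifnot(inherits(params, "stratification_params"))
  if (is.unsorted(depths, strictly = TRUE) || any(depths < 0))
    stop("depths must be non-negative and strictly increasing")
  shape <- function(z) (1 - tanh((z - params$thermocline_depth) /
                                   params$thermocline_width)) / 2
  s0 <- shape(0)
  w <- shape(depths) / s0
  hydro_profile(depths,
                temp = params$deep_t + (params$sst - params$deep_t) * w,
                sal = params$deep_s + (params$sss - params$deep_s) * w,
                station = station)
}

# closest-approach day of the track to every grid pixel, evaluated on the
# series' own daily time grid (so injected lags are exact in days)
closest_approach_day <- function(track, grid, times) {
  tp <- as.POSIXct(times, tz = "UTC")
  inside <- tp >= track$time[1] & tp <= track$time[nrow(track)]
  if (!any(inside))
    stop("no requested time falls within the track's time span")
  pos <- track_position(track, tp[inside])
  nlat <- length(grid$lats); nlon <- length(grid$lons)
  latv <- rep(grid$lats, times = nlon)
  lonv <- rep(grid$lons, each = nlat)
  dmin <- matrix(Inf, nlat, nlon)
  tca <- matrix(NA_real_, nlat, nlon)
  day <- as.numeric(times)
  for (k in seq_len(nrow(pos))) {
    d <- matrix(haversine(latv, lonv, pos$lat[k], pos$lon[k]), nlat, nlon)
    upd <- d < dmin
    dmin[upd] <- d[upd]
    tca[upd] <- day[inside][k]
  }
  tca
}

#' Cloud-masked lagged chlorophyll-a fields
#'
#' Every pixel's chlorophyll rises linearly from `baseline_chl` (at the
#' cyclone's closest approach to the pixel) to `peak_chl` after `lag_days`
#' days, then relaxes exponentially back toward baseline. Each pixel-day is
#' independently masked (`NA`) with probability `cloud_fraction` using the
#' scenario's seed; calls with the same seed are bit-identical, and the
#' global RNG state is untouched.
#'
#' @param track A [tc_track()].
#' @param scenario A [bloom_scenario()].
#' @param grid A [geo_grid()].
#' @param times A daily `Date` (or daily-spaced) time vector overlapping the
#'   track's span.
#' @return A [scalar_series()] of chlorophyll-a, mg m^-3, with attribute
#'   `tca` (matrix of per-pixel closest-approach days, numeric time units).
#' @export
gen_bloom_fields <- function(track, scenario, grid, times) {
  stopifnot(inherits(scenario, "bloom_scenario"), inherits(grid, "geo_grid"))
  tca <- closest_approach_day(track, grid, times)
  day <- as.numeric(times)
  dsec <- diff(day)
  cadence <- if (inherits(times, "POSIXct")) 86400 else 1
  if (length(dsec) && max(abs(dsec - cadence)) > 1e-6)
    stop("times must be daily")
  nlat <- length(grid$lats); nlon <- length(grid$lons); nt <- length(times)
  delta <- scenario$peak_chl - scenario$baseline_chl
  lag <- scenario$lag_days * cadence
  efold <- scenario$efold_days * cadence
  data <- array(NA_real_, c(nlat, nlon, nt))
  for (k in seq_len(nt)) {
    phase <- day[k] - tca
    chl <- matrix(scenario$baseline_chl, nlat, nlon)
    if (lag > 0) {
      rising <- phase >= 0 & phase <= lag
      chl[rising] <- scenario$baseline_chl + delta * phase[rising] / lag
    }
    post <- if (lag > 0) phase > lag else phase >= 0
    chl[post] <- scenario$baseline_chl +
      delta * exp(-(phase[post] - lag) / efold)
    data[, , k] <- chl
  }
  if (scenario$cloud_fraction > 0) {
    mask <- with_seed(scenario$seed,
                      array(stats::runif(nlat * nlon * nt) <
                              scenario$cloud_fraction, c(nlat, nlon, nt)))
    data[mask] <- NA_real_
  }
  out <- scalar_series(grid, data, times, "chl", "mg m-3")
  attr(out, "tca") <- tca
  out
}

#' Storm-cooled sea surface temperature fields
#'
#' Injects a step cooling of known magnitude and duration: SST equals
#' `baseline` everywhere except during the `duration_days` days starting
#' `onset_lag_days` after each pixel's closest-approach day, when it is
#' `baseline - drop`. The one-day default onset lag reflects that
#' storm-induced surface cooling develops over the hours to a day following
#' passage, and keeps the passage day itself uncontaminated for baseline
#' estimation. Small
#' Gaussian pixel noise (`noise_sd`) is added so box averages exercise the
#' masking/weighting machinery without obscuring the injected ground truth.
#'
#' @param track A [tc_track()].
#' @param grid A [geo_grid()].
#' @param times Daily time vector overlapping the track's span.
#' @param baseline Undisturbed SST, degC (default 29).
#' @param drop Injected cooling magnitude, degC (default 2).
#' @param duration_days Whole days the cooling persists (default 10).
#' @param onset_lag_days Whole days between local closest approach and
#'   cooling onset (default 1).
#' @param noise_sd Per-pixel Gaussian noise, degC (default 0.02).
#' @param seed RNG seed for the noise.
#' @return A [scalar_series()] of SST, degC, with attribute `tca`.
#' @export
gen_sst_field <- function(track, grid, times, baseline = 29, drop = 2,
                          duration_days = 10, onset_lag_days = 1,
                          noise_sd = 0.02, seed = 1) {
  stopifnot(inherits(grid, "geo_grid"), drop >= 0, duration_days >= 0)
  tca <- closest_approach_day(track, grid, times)
  day <- as.numeric(times)
  cadence <- if (inherits(times, "POSIXct")) 86400 else 1
  nlat <- length(grid$lats); nlon <- length(grid$lons); nt <- length(times)
  data <- array(baseline, c(nlat, nlon, nt))
  for (k in seq_len(nt)) {
    phase <- day[k] - tca - onset_lag_days * cadence
    cooled <- phase >= 0 & phase < duration_days * cadence
    slice <- data[, , k]
    slice[cooled] <- baseline - drop
    data[, , k] <- slice
  }
  if (noise_sd > 0)
    data <- data + with_seed(seed, array(stats::rnorm(length(data), 0,
                                                      noise_sd), dim(data)))
  out <- scalar_series(grid, data, times, "sst", "degC")
  attr(out, "tca") <- tca
  out
}

#' Storm-locked pulse fields (PAR dip, precipitation spike)
#'
#' A generic generator for the remaining forcing inputs: a field equal to
#' `base` plus a Gaussian-in-time pulse of height `amplitude` (negative for
#' a PAR drop, positive for a rain spike) centred on each pixel's
#' closest-approach day with temporal half-width `width_days`.
#'
#' @param track A [tc_track()].
#' @param grid A [geo_grid()].
#' @param times Daily time vector overlapping the track's span.
#' @param base Background value (e.g. 45 Einstein m-2 day-1 for PAR, 0 mm
#'   day-1 for precipitation).
#' @param amplitude Pulse height in field units.
#' @param width_days Temporal standard deviation of the pulse, days.
#' @param varname,units Metadata for the output series.
#' @return A [scalar_series()].
#' @export
gen_pulse_field <- function(track, grid, times, base, amplitude,
                            width_days = 1.5, varname = "par", units = "") {
  stopifnot(inherits(grid, "geo_grid"), width_days > 0)
  tca <- closest_approach_day(track, grid, times)
  day <- as.numeric(times)
  cadence <- if (inherits(times, "POSIXct")) 86400 else 1
  nlat <- length(grid$lats); nlon <- length(grid$lons); nt <- length(times)
  data <- array(NA_real_, c(nlat, nlon, nt))
  for (k in seq_len(nt)) {
    phase <- (day[k] - tca) / cadence
    data[, , k] <- base + amplitude * exp(-phase^2 / (2 * width_days^2))
  }
  scalar_series(grid, data, times, varname, units)
}
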