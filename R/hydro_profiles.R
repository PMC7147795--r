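#' Depth-ordered temperature/salinity profile
#'
#' @param depth Depths in metres, positive down, strictly increasing,
#'   length >= 3.
#' @param temp In-situ temperature, deg C.
#' @param sal Practical salinity, psu.
#' @param station Optional list with `lat`, `lon`, `time` metadata.
#' @return An object of class `hydro_profile`.
#' @export
hydro_profile <- function(depth, temp, sal, station = NULL) {
  n <- length(depth)
  if (n < 3L) stop("a profile needs at least 3 levels")
  if (length(temp) != n || length(sal) != n)
    stop("depth, temp, sal must have equal length")
  if (is.unsorted(depth, strictly = TRUE))
    stop("depths must be strictly increasing (positive down)")
  structure(list(depth = as.numeric(depth), temp = as.numeric(temp),
                 sal = as.numeric(sal), station = station),
            class = "hydro_profile")
}

#' @export
print.hydro_profile <- function(x, ...) {
  cat(sprintf("<hydro_profile> %d levels, %g-%g m; T %g-%g degC, S %g-%g psu\n",
              length(x$depth), min(x$depth), max(x$depth),
              min(x$temp), max(x$temp), min(x$sal), max(x$sal)))
  invisible(x)
}

# linear equation of state coefficients (rho0 is the Ekman-pumping seawater
# density constant so the two modules share one reference density)
.eos_linear <- list(rho0 = 1024, alpha = 2.0e-4, beta = 7.6e-4,
                    t0 = 20, s0 = 35)

#' Seawater density from a profile
#'
#' The default linear equation of state,
#' rho = rho0 * (1 - alpha (T - T0) + beta (S - S0)) with rho0 = 1024 kg m^-3,
#' alpha = 2.0e-4 /degC, beta = 7.6e-4 /psu, T0 = 20 degC, S0 = 35 psu,
#' keeps every stratification oracle analytic. `eos = "teos10"` delegates to
#' the `gsw` package when it is installed and errors otherwise.
#'
#' @param profile A [hydro_profile()].
#' @param eos `"linear"` or `"teos10"`.
#' @return Density in kg m^-3, one value per level.
#' @export
sw_density <- function(profile, eos = c("linear", "teos10")) {
  eos <- match.arg(eos)
  stopifnot(inherits(profile, "hydro_profile"))
  if (eos == "linear") {
    p <- .eos_linear
    p$rho0 * (1 - p$alpha * (profile$temp - p$t0) +
                p$beta * (profile$sal - p$s0))
  } else {
    if (!requireNamespace("gsw", quietly = TRUE))
      stop("eos = 'teos10' requires the 'gsw' package, which is not installed")
    lat <- profile$station$lat %||% 0
    lon <- profile$station$lon %||% 0
    p_dbar <- gsw::gsw_p_from_z(-profile$depth, lat)
    sa <- gsw::gsw_SA_from_SP(profile$sal, p_dbar, lon, lat)
    ct <- gsw::gsw_CT_from_t(sa, profile$temp, p_dbar)
    gsw::gsw_rho(sa, ct, p_dbar)
  }
}

#' Buoyancy (Brunt-Vaisala) frequency profile
#'
#' N^2 = (g / rho0) * d(rho)/dz with z positive down, so stable
#' stratification (density increasing downward) gives N^2 > 0. The vertical
#' derivative uses first differences between adjacent levels, valued at the
#' layer midpoints. Unstable layers (N^2 < 0) are reported as N = 0 and
#' flagged rather than returned as NaN, which keeps the thermocline argmax
#' well defined.
#'
#' @param profile A [hydro_profile()].
#' @param eos Equation of state, see [sw_density()].
#' @param smooth Apply a 3-point running mean to N^2 (default FALSE; real
#'   float data usually needs it, synthetic profiles do not).
#' @return An object of class `n_profile`: list with `depth_mid` (m), `n`
#'   (s^-1), `n2` (s^-2, signed), and `unstable` (logical per midpoint).
#' @export
buoyancy_frequency <- function(profile, eos = c("linear", "teos10"),
                               smooth = FALSE) {
  eos <- match.arg(eos)
  rho <- sw_density(profile, eos)
  g <- 9.81
  rho0 <- .eos_linear$rho0
  dz <- diff(profile$depth)
  n2 <- (g / rho0) * diff(rho) / dz
  if (smooth && length(n2) >= 3L) {
    n2 <- stats::filter(n2, rep(1 / 3, 3), sides = 2)
    n2[1L] <- n2[2L]
    n2[length(n2)] <- n2[length(n2) - 1L]
    n2 <- as.numeric(n2)
  }
  structure(list(depth_mid = profile$depth[-length(profile$depth)] + dz / 2,
                 n = sqrt(pmax(n2, 0)), n2 = n2, unstable = n2 < 0),
            class = "n_profile")
}

#' Thermocline depth from a buoyancy-frequency profile
#'
#' The midpoint depth at which N is maximal; ties broken toward the
#' shallowest midpoint. An unstratified profile (N identically 0) has no
#' thermocline: the return value is `NA` with attribute
#' `status = "unstratified"`.
#'
#' @param n_profile An `n_profile` from [buoyancy_frequency()].
#' @return Depth in metres (or flagged `NA`).
#' @export
thermocline_depth <- function(n_profile) {
  stopifnot(inherits(n_profile, "n_profile"))
  if (all(n_profile$n == 0))
    return(structure(NA_real_, status = "unstratified"))
  # which.max takes the first (shallowest) of tied maxima; depths ascend
  n_profile$depth_mid[which.max(n_profile$n)]
}

#' Mixed-layer depth by temperature threshold
#'
#' The shallowest depth at which temperature falls more than `dT` below the
#' temperature at reference depth `zref` (defaults 0.2 degC from 10 m, the
#' de-facto community criterion), linearly interpolated between levels. If
#' the criterion is never met the profile is flagged: `NA` with attribute
#' `status = "deeper_than_profile"`.
#'
#' @param profile A [hydro_profile()] reaching below `zref`.
#' @param dT Temperature threshold, degC (default 0.2).
#' @param zref Reference depth, m (default 10).
#' @return MLD in metres (or flagged `NA`).
#' @export
mixed_layer_depth <- function(profile, dT = 0.2, zref = 10) {
  stopifnot(inherits(profile, "hydro_profile"), dT > 0)
  if (max(profile$depth) <= zref)
    stop("profile does not reach below the reference depth")
  tref <- stats::approx(profile$depth, profile$temp, xout = zref,
                        rule = 2)$y
  thresh <- tref - dT
  below <- which(profile$depth >= zref)
  hit <- below[profile$temp[below] < thresh]
  if (!length(hit))
    return(structure(NA_real_, status = "deeper_than_profile"))
  i <- hit[1L]
  if (i == 1L) return(profile$depth[1L])
  # linear interpolation between the bracketing levels
  z0 <- profile$depth[i - 1L]; z1 <- profile$depth[i]
  t0 <- profile$temp[i - 1L]; t1 <- profile$temp[i]
  z0 + (thresh - t0) * (z1 - z0) / (t1 - t0)
}

#' Stratification summary of a profile
#'
#' Bundles the diagnostics used in the upper-ocean response analysis:
#' the N(z) profile, the thermocline depth (argmax of N), the maximum
#' buoyancy frequency, and the mixed-layer depth.
#'
#' @param profile A [hydro_profile()].
#' @param eos Equation of state, see [sw_density()].
#' @param dT,zref Mixed-layer criterion, see [mixed_layer_depth()].
#' @return An object of class `stratification_summary`: list with
#'   `n_profile`, `thermocline_depth` (m), `n_max` (s^-1), `mld` (m).
#' @export
stratification_summary <- function(profile, eos = "linear", dT = 0.2,
                                   zref = 10) {
  np <- buoyancy_frequency(profile, eos)
  structure(list(n_profile = np,
                 thermocline_depth = thermocline_depth(np),
                 n_max = max(np$n),
                 mld = mixed_layer_depth(profile, dT, zref)),
            class = "stratification_summary")
}

#' @export
print.stratification_summary <- function(x, ...) {
  cat(sprintf(
    "<stratification_summary> thermocline %.1f m, N_max %.4g s-1, MLD %s m\n",
    x$thermocline_depth, x$n_max,
    if (is.na(x$mld)) "NA" else sprintf("%.1f", x$mld)))
  invisible(x)
}
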