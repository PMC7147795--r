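#' Physical constants for Ekman pumping
#'
#' @param rho_sw Seawater density, kg m^-3 (default 1024).
#' @param omega Earth rotation rate, s^-1, for f = 2 Omega sin(phi).
#' @param rho_air Surface air density, kg m^-3 (default 1.2).
#' @param cd_scheme Drag-coefficient rule: `"constant"` (Cd = 1.3e-3) or
#'   `"largepond"` (piecewise-linear in wind speed, capped at 25 m s^-1).
#' @return An object of class `epv_constants`.
#' @export
epv_constants <- function(rho_sw = 1024, omega = 7.2921e-5, rho_air = 1.2,
                          cd_scheme = c("constant", "largepond")) {
  cd_scheme <- match.arg(cd_scheme)
  stopifnot(rho_sw > 0, is.finite(omega), is.finite(rho_air), rho_air > 0)
  structure(list(rho_sw = rho_sw, omega = omega, rho_air = rho_air,
                 cd_scheme = cd_scheme),
            class = "epv_constants")
}

#' Drag coefficient as a function of 10-m wind speed
#'
#' `"constant"` returns 1.3e-3 everywhere (keeps analytic oracles exact).
#' `"largepond"` is a piecewise-linear bulk scheme: 1.2e-3 below 11 m s^-1,
#' then (0.49 + 0.065 U) * 1e-3, held fixed above 25 m s^-1 where bulk
#' extrapolation is unreliable.
#'
#' @param speed Wind speed, m s^-1.
#' @param scheme `"constant"` or `"largepond"`.
#' @return Dimensionless Cd, same shape as `speed`.
#' @export
drag_coefficient <- function(speed, scheme = c("constant", "largepond")) {
  scheme <- match.arg(scheme)
  if (scheme == "constant") {
    cd <- array(1.3e-3, dim = dim(speed) %||% length(speed))
  } else {
    cd <- (0.49 + 0.065 * pmin(pmax(speed, 11), 25)) * 1e-3
    cd[speed < 11] <- 1.2e-3
  }
  cd
}

#' Surface wind stress from 10-m winds
#'
#' Bulk quadratic law: (tau_x, tau_y) = rho_air * Cd(|U|) * |U| * (u, v).
#' Masked wind pixels stay masked in the stress.
#'
#' @param wind A [vector_series()] of 10-m winds (m s^-1).
#' @param consts An [epv_constants()] giving `rho_air` and `cd_scheme`.
#' @return A [vector_series()] of stress components in N m^-2.
#' @export
wind_stress <- function(wind, consts = epv_constants()) {
  stopifnot(inherits(wind, "vector_series"), inherits(consts, "epv_constants"))
  spd <- sqrt(wind$u^2 + wind$v^2)
  cd <- drag_coefficient(spd, consts$cd_scheme)
  fac <- consts$rho_air * cd * spd
  vector_series(wind$grid, fac * wind$u, fac * wind$v, wind$times,
                varname = "tau", units = "N m-2")
}

# partial derivative wrt longitude (radians), centered interior / one-sided
# edges, applied slice-wise to a [nlat, nlon] matrix. NA poisons the stencil.
ddlambda <- function(m, dlon_deg) {
  h <- deg2rad(dlon_deg)
  n <- ncol(m)
  out <- m * NA_real_
  if (n >= 3L) out[, 2:(n - 1L)] <- (m[, 3:n] - m[, 1:(n - 2L)]) / (2 * h)
  out[, 1L] <- (m[, 2L] - m[, 1L]) / h
  out[, n] <- (m[, n] - m[, n - 1L]) / h
  out
}

# partial derivative wrt latitude (radians); rows are latitudes, ascending
ddphi <- function(m, dlat_deg) {
  h <- deg2rad(dlat_deg)
  n <- nrow(m)
  out <- m * NA_real_
  if (n >= 3L) out[2:(n - 1L), ] <- (m[3:n, ] - m[1:(n - 2L), ]) / (2 * h)
  out[1L, ] <- (m[2L, ] - m[1L, ]) / h
  out[n, ] <- (m[n, ] - m[n - 1L, ]) / h
  out
}

#' Wind-stress curl on the sphere
#'
#' curl(tau) = 1/(R cos phi) * [ d(tau_y)/d(lambda) - d(tau_x cos phi)/d(phi) ],
#' with phi latitude and lambda longitude in radians. The phi derivative is
#' applied to the product tau_x cos(phi), not expanded. Centered 2nd-order
#' differences at interior points, 1st-order one-sided at grid edges; any
#' stencil touching a masked pixel yields a masked result.
#'
#' @param stress A [vector_series()] of stress components (N m^-2), e.g. from
#'   [wind_stress()].
#' @return A [scalar_series()] of curl values in N m^-3.
#' @export
wind_stress_curl <- function(stress) {
  stopifnot(inherits(stress, "vector_series"))
  grid <- stress$grid
  if (any(abs(abs(grid$lats) - 90) < 1e-9))
    stop("grid touches a pole (cos phi = 0); curl undefined there")
  cosphi <- cos(deg2rad(grid$lats))
  nt <- dim(stress$u)[3]
  out <- array(NA_real_, dim(stress$u))
  for (k in seq_len(nt)) {
    tx <- stress$u[, , k]
    ty <- stress$v[, , k]
    term1 <- ddlambda(ty, grid$dlon)
    term2 <- ddphi(tx * cosphi, grid$dlat)
    out[, , k] <- (term1 - term2) / (grid$radius * cosphi)
  }
  scalar_series(grid, out, stress$times, varname = "curl_tau", units = "N m-3")
}

#' Ekman pumping velocity from the wind-stress curl
#'
#' w_E = curl(tau) / (rho_sw * f), evaluated per grid row, in m s^-1.
#' Positive values are upwelling in the Northern Hemisphere. Rows with
#' |latitude| below `equator_mask_deg` are masked because f vanishes at the
#' equator.
#'
#' @param curl A [scalar_series()] of wind-stress curl (N m^-3), from
#'   [wind_stress_curl()].
#' @param consts An [epv_constants()] giving `rho_sw` and `omega`.
#' @param equator_mask_deg Mask half-width around the equator, degrees
#'   (default 2).
#' @return A [scalar_series()] of w_E in m s^-1.
#' @export
ekman_pumping <- function(curl, consts = epv_constants(),
                          equator_mask_deg = 2) {
  stopifnot(inherits(curl, "scalar_series"), inherits(consts, "epv_constants"))
  grid <- curl$grid
  f <- coriolis(grid$lats, consts$omega)
  inv <- 1 / (consts$rho_sw * f)
  inv[abs(grid$lats) < equator_mask_deg] <- NA_real_
  out <- curl$data * array(rep(inv, times = prod(dim(curl$data)[2:3])),
                           dim = dim(curl$data))
  scalar_series(grid, out, curl$times, varname = "w_E", units = "m s-1")
}
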