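#' Relative vorticity of a current field
#'
#' Vertical component of the curl of the horizontal current, computed with
#' the full spherical metric so it is grid-consistent with the wind-stress
#' curl:
#'
#'   curl_z = (1 / (R cos phi)) dv/dlambda - (1/R) du/dphi + u tan(phi) / R
#'
#' which reduces locally to the planar dv/dx - du/dy. Computed independently
#' at every depth level and time. Centered differences at interior points,
#' one-sided at edges; masked pixels poison their stencil.
#'
#' @param currents A [current_field()].
#' @return An array of curl_z values in s^-1 with the same
#'   `[nlat, nlon, ndepth, ntime]` dimensions, with the grid, depth and time
#'   axes attached as attributes `grid`, `depths`, `times`.
#' @examples
#' g <- geo_grid(seq(10, 12, 0.25), seq(67, 69, 0.25))
#' ssh_cur <- gen_eddy_ssh_currents(list(eddy_spec(c(11, 68), -0.1, 60)), g)
#' vort <- relative_vorticity(ssh_cur$currents)
#' vort[5, 5, 1, 1] > 0  # cyclonic at the eddy centre
#' @export
relative_vorticity <- function(currents) {
  stopifnot(inherits(currents, "current_field"))
  grid <- currents$grid
  if (any(abs(abs(grid$lats) - 90) < 1e-9))
    stop("grid touches a pole; vorticity metric undefined there")
  phi <- deg2rad(grid$lats)
  cosphi <- cos(phi)
  tanphi <- tan(phi)
  d <- dim(currents$u)
  out <- array(NA_real_, d)
  for (it in seq_len(d[4])) {
    for (iz in seq_len(d[3])) {
      u <- currents$u[, , iz, it]
      v <- currents$v[, , iz, it]
      out[, , iz, it] <- ddlambda(v, grid$dlon) / (grid$radius * cosphi) -
        ddphi(u, grid$dlat) / grid$radius +
        u * tanphi / grid$radius
    }
  }
  attr(out, "grid") <- grid
  attr(out, "depths") <- currents$depths
  attr(out, "times") <- currents$times
  out
}

#' Box-averaged positive-vorticity section
#'
#' Summarises a vorticity array as the intensity of cyclonic circulation in
#' a box: for every (time, depth) pair, an area-weighted (cos phi) average
#' over the box's unmasked pixels, restricted to positive vorticity. Two
#' statistics are offered:
#'
#' * `pos_conditional_mean` (default): mean over pixels with curl_z > 0 —
#'   tracks eddy-core intensity; 0 when no pixel is positive.
#' * `rectified_mean`: mean of max(curl_z, 0) over all unmasked pixels.
#'
#' @param vort A vorticity array from [relative_vorticity()] (grid/depth/time
#'   attributes required).
#' @param box A [box_region()].
#' @param statistic `"pos_conditional_mean"` or `"rectified_mean"`.
#' @return An object of class `vorticity_section`: a list with `values`
#'   (matrix `[ntime, ndepth]`, s^-1), `times`, `depths`, `box`, `statistic`.
#' @export
positive_vorticity_box_mean <- function(vort, box,
                                        statistic = c("pos_conditional_mean",
                                                      "rectified_mean")) {
  statistic <- match.arg(statistic)
  grid <- attr(vort, "grid")
  depths <- attr(vort, "depths")
  times <- attr(vort, "times")
  if (is.null(grid)) stop("vort must carry a 'grid' attribute (see relative_vorticity)")
  stopifnot(inherits(box, "box_region"))
  idx <- box_index(grid, box)
  w <- cos(deg2rad(grid$lats[idx$ilat]))
  wmat <- matrix(w, nrow = sum(idx$ilat), ncol = sum(idx$ilon))
  d <- dim(vort)
  values <- matrix(NA_real_, nrow = d[4], ncol = d[3])
  for (it in seq_len(d[4])) {
    for (iz in seq_len(d[3])) {
      z <- vort[idx$ilat, idx$ilon, iz, it]
      ok <- is.finite(z)
      if (!any(ok)) { values[it, iz] <- NA_real_; next }
      if (statistic == "pos_conditional_mean") {
        pos <- ok & z > 0
        values[it, iz] <- if (any(pos))
          sum(z[pos] * wmat[pos]) / sum(wmat[pos]) else 0
      } else {
        values[it, iz] <- sum(pmax(z[ok], 0) * wmat[ok]) / sum(wmat[ok])
      }
    }
  }
  structure(list(values = values, times = times, depths = depths,
                 box = box, statistic = statistic),
            class = "vorticity_section")
}

#' @export
print.vorticity_section <- function(x, ...) {
  cat(sprintf("<vorticity_section '%s'> %d time(s) x %d depth(s); max %.3g s-1\n",
              x$statistic, nrow(x$values), ncol(x$values),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}
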