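#' Gridded scalar field series
#'
#' A time-stamped stack of 2-D scalar fields (SSH, SST, chlorophyll-a, PAR,
#' precipitation, wind-stress curl, Ekman pumping velocity, ...) on a
#' [geo_grid()]. Missing (e.g. cloud-masked) pixels are `NA`.
#'
#' @param grid A [geo_grid()].
#' @param data Numeric array `[nlat, nlon, ntime]` (a matrix is promoted to a
#'   single time slice). `NA` marks masked pixels.
#' @param times Vector of time stamps, length `ntime` (`Date`, `POSIXct` or
#'   numeric). A single-slice field may omit it.
#' @param varname,units Optional variable name and units strings, carried
#'   through I/O.
#' @return An object of class `scalar_series`.
#' @export
scalar_series <- function(grid, data, times = NULL, varname = "value",
                          units = "") {
  stopifnot(inherits(grid, "geo_grid"))
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3L)
  if (dim(data)[1] != length(grid$lats) || dim(data)[2] != length(grid$lons))
    stop("data dimensions do not match the grid")
  if (is.null(times)) times <- seq_len(dim(data)[3])
  if (length(times) != dim(data)[3])
    stop("length(times) must equal the third data dimension")
  structure(list(grid = grid, data = data, times = times,
                 varname = varname, units = units),
            class = "scalar_series")
}

#' Gridded vector field series
#'
#' Zonal/meridional component pairs (10-m wind, surface stress, surface
#' currents) on a [geo_grid()], sharing the mask semantics of
#' [scalar_series()].
#'
#' @param grid A [geo_grid()].
#' @param u,v Numeric arrays `[nlat, nlon, ntime]` (matrices promoted).
#' @param times Time stamps, length `ntime`.
#' @param varname,units Optional metadata strings.
#' @return An object of class `vector_series`.
#' @export
vector_series <- function(grid, u, v, times = NULL, varname = "uv",
                          units = "") {
  stopifnot(inherits(grid, "geo_grid"))
  if (is.matrix(u)) u <- array(u, dim = c(dim(u), 1L))
  if (is.matrix(v)) v <- array(v, dim = c(dim(v), 1L))
  if (!identical(dim(u), dim(v))) stop("u and v must have identical dims")
  if (dim(u)[1] != length(grid$lats) || dim(u)[2] != length(grid$lons))
    stop("u/v dimensions do not match the grid")
  if (is.null(times)) times <- seq_len(dim(u)[3])
  if (length(times) != dim(u)[3])
    stop("length(times) must equal the third data dimension")
  structure(list(grid = grid, u = u, v = v, times = times,
                 varname = varname, units = units),
            class = "vector_series")
}

#' @export
print.scalar_series <- function(x, ...) {
  cat(sprintf("<scalar_series '%s'%s> %d x %d x %d times; %.1f%% masked\n",
              x$varname, if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              100 * mean(is.na(x$data))))
  invisible(x)
}

#' @export
print.vector_series <- function(x, ...) {
  cat(sprintf("<vector_series '%s'%s> %d x %d x %d times; %.1f%% masked\n",
              x$varname, if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              dim(x$u)[1], dim(x$u)[2], dim(x$u)[3],
              100 * mean(is.na(x$u))))
  invisible(x)
}

#' Depth-resolved current field
#'
#' Horizontal currents u, v on a [geo_grid()] with an optional depth axis
#' (metres, positive down, ascending) and time axis, as produced by gridded
#' reanalysis products. Used by [relative_vorticity()] and
#' [positive_vorticity_box_mean()].
#'
#' @param grid A [geo_grid()].
#' @param u,v Numeric arrays `[nlat, nlon, ndepth, ntime]`. Lower-rank input
#'   is promoted: a matrix becomes one depth, one time; a 3-D array is taken
#'   as `[nlat, nlon, ndepth]` at one time.
#' @param depths Depth axis (m, positive down, ascending); default a single
#'   surface level 0.
#' @param times Time stamps, length `ntime`.
#' @return An object of class `current_field`.
#' @export
current_field <- function(grid, u, v, depths = NULL, times = NULL) {
  stopifnot(inherits(grid, "geo_grid"))
  promote <- function(a) {
    if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L, 1L))
    else if (length(dim(a)) == 3L) a <- array(a, dim = c(dim(a), 1L))
    a
  }
  u <- promote(u); v <- promote(v)
  if (!identical(dim(u), dim(v))) stop("u and v must have identical dims")
  if (dim(u)[1] != length(grid$lats) || dim(u)[2] != length(grid$lons))
    stop("u/v dimensions do not match the grid")
  if (is.null(depths)) depths <- if (dim(u)[3] == 1L) 0 else seq_len(dim(u)[3])
  if (length(depths) != dim(u)[3]) stop("depths length mismatch")
  if (is.unsorted(depths, strictly = TRUE)) stop("depths must be ascending")
  if (is.null(times)) times <- seq_len(dim(u)[4])
  if (length(times) != dim(u)[4]) stop("times length mismatch")
  structure(list(grid = grid, u = u, v = v, depths = depths, times = times),
            class = "current_field")
}

#' @export
print.current_field <- function(x, ...) {
  cat(sprintf("<current_field> %d x %d, %d depth(s), %d time(s)\n",
              dim(x$u)[1], dim(x$u)[2], dim(x$u)[3], dim(x$u)[4]))
  invisible(x)
}
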