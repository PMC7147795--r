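# times on a day scale regardless of representation
time_days <- function(times) {
  if (inherits(times, "POSIXct")) as.numeric(times) / 86400
  else as.numeric(times)
}

#' Box-averaged time series of a gridded field
#'
#' For every time slice, the cos(latitude) area-weighted mean of the field
#' over unmasked pixels whose centres fall inside the box (bounds inclusive).
#' A fully masked slice yields a missing value with `n_valid = 0`.
#'
#' @param field A [scalar_series()].
#' @param box A [box_region()] overlapping the field's grid.
#' @return An object of class `box_series`: a data.frame with columns `time`,
#'   `value` and `n_valid` (count of unmasked contributing pixels).
#' @export
box_mean <- function(field, box) {
  stopifnot(inherits(field, "scalar_series"))
  idx <- box_index(field$grid, box)
  w <- cos(deg2rad(field$grid$lats[idx$ilat]))
  wmat <- matrix(w, nrow = sum(idx$ilat), ncol = sum(idx$ilon))
  nt <- dim(field$data)[3]
  value <- numeric(nt); n_valid <- integer(nt)
  for (k in seq_len(nt)) {
    z <- field$data[idx$ilat, idx$ilon, k]
    ok <- is.finite(z)
    n_valid[k] <- sum(ok)
    value[k] <- if (any(ok)) sum(z[ok] * wmat[ok]) / sum(wmat[ok]) else NA_real_
  }
  out <- data.frame(time = field$times, value = value, n_valid = n_valid)
  class(out) <- c("box_series", "data.frame")
  out
}

#' Two-day (gap-aware) composite of a gridded field over a box
#'
#' Cloud gaps in daily ocean-colour fields are mitigated by compositing
#' consecutive days. Windows of `window` days are anchored at the first time
#' and tile the record (non-overlapping) by default; `sliding = TRUE` gives
#' a daily-stepping window instead. Within a window the default `"pooled"`
#' statistic is the area-weighted mean over *all* unmasked pixel-days pooled
#' across the window — not the mean of daily means — so a fully clouded day
#' is rescued by its neighbour. `"daily_means"` averages the per-day box
#' means instead. A window with zero valid pixel-days is missing.
#'
#' @param field A [scalar_series()] at daily cadence.
#' @param box A [box_region()].
#' @param window Window length in days (default 2).
#' @param method `"pooled"` (default) or `"daily_means"`.
#' @param sliding Logical; daily-sliding windows instead of tiling.
#' @return A `box_series` whose `time` column holds each window's first day
#'   and whose `n_valid` counts pooled valid pixel-days.
#' @export
two_day_composite <- function(field, box, window = 2,
                              method = c("pooled", "daily_means"),
                              sliding = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(field, "scalar_series"), window >= 1)
  td <- time_days(field$times)
  if (length(td) > 1 && max(abs(diff(td) - 1)) > 1e-6)
    stop("two_day_composite expects daily cadence")
  idx <- box_index(field$grid, box)
  w <- cos(deg2rad(field$grid$lats[idx$ilat]))
  wmat <- matrix(w, nrow = sum(idx$ilat), ncol = sum(idx$ilon))
  nt <- dim(field$data)[3]
  starts <- if (sliding) seq_len(max(1L, nt - window + 1L))
            else seq(1L, nt, by = window)
  value <- numeric(length(starts)); n_valid <- integer(length(starts))
  for (j in seq_along(starts)) {
    ks <- starts[j]:min(nt, starts[j] + window - 1L)
    if (method == "pooled") {
      num <- 0; den <- 0; nv <- 0L
      for (k in ks) {
        z <- field$data[idx$ilat, idx$ilon, k]
        ok <- is.finite(z)
        num <- num + sum(z[ok] * wmat[ok])
        den <- den + sum(wmat[ok])
        nv <- nv + sum(ok)
      }
      n_valid[j] <- nv
      value[j] <- if (den > 0) num / den else NA_real_
    } else {
      bm <- vapply(ks, function(k) {
        z <- field$data[idx$ilat, idx$ilon, k]
        ok <- is.finite(z)
        if (any(ok)) sum(z[ok] * wmat[ok]) / sum(wmat[ok]) else NA_real_
      }, numeric(1))
      n_valid[j] <- sum(!is.na(bm))
      value[j] <- if (any(!is.na(bm))) mean(bm, na.rm = TRUE) else NA_real_
    }
  }
  out <- data.frame(time = field$times[starts], value = value,
                    n_valid = n_valid)
  class(out) <- c("box_series", "data.frame")
  out
}

# baseline over the window of `window` days ending at (and including) passage
series_baseline <- function(series, passage, window) {
  td <- time_days(series$time)
  tp <- time_days(passage)
  sel <- td > tp - window & td <= tp & !is.na(series$value)
  if (!any(sel)) stop("no valid values in the baseline window")
  mean(series$value[sel])
}

#' Bloom lag and fold-increase metrics
#'
#' From a box-averaged chlorophyll series: the baseline is the mean of valid
#' values in the `baseline_window` days ending at the passage time, the peak
#' is the maximum valid value after passage (ties broken to the earliest
#' time), the fold increase is peak/baseline, and the lag is the peak time
#' minus the passage time in days.
#'
#' @param chl A `box_series` of chlorophyll-a.
#' @param tc_passage_time Passage time (same representation as the series
#'   times).
#' @param baseline_window Baseline window length, days (default 6).
#' @return An object of class `bloom_metrics`: list with `baseline`,
#'   `peak_value`, `peak_time`, `fold_increase`, `lag_days`.
#' @export
bloom_metrics <- function(chl, tc_passage_time, baseline_window = 6) {
  stopifnot(inherits(chl, "box_series"))
  baseline <- series_baseline(chl, tc_passage_time, baseline_window)
  if (baseline <= 0) stop("baseline must be positive for a fold increase")
  td <- time_days(chl$time)
  tp <- time_days(tc_passage_time)
  post <- which(td > tp & !is.na(chl$value))
  if (!length(post)) stop("no valid values after the passage time")
  ipeak <- post[which.max(chl$value[post])] # which.max ties to earliest
  structure(list(baseline = baseline,
                 peak_value = chl$value[ipeak],
                 peak_time = chl$time[ipeak],
                 fold_increase = chl$value[ipeak] / baseline,
                 lag_days = td[ipeak] - tp),
            class = "bloom_metrics")
}

#' @export
print.bloom_metrics <- function(x, ...) {
  cat(sprintf(
    "<bloom_metrics> baseline %.3g, peak %.3g (x%.1f) %g days after passage\n",
    x$baseline, x$peak_value, x$fold_increase, x$lag_days))
  invisible(x)
}

#' Storm-cooling magnitude and persistence
#'
#' From a box-averaged SST series: `max_drop` is the baseline minus the
#' post-passage minimum, and `persistence_days` is the length (in days) of
#' the longest contiguous run of valid post-passage samples colder than
#' baseline minus `recovery_margin`.
#'
#' @param sst A `box_series` of SST.
#' @param tc_passage_time Passage time.
#' @param baseline_window Baseline window length, days (default 6).
#' @param recovery_margin Cooling considered over when SST recovers to within
#'   this margin of baseline, degC (default 0.5).
#' @return An object of class `cooling_metrics`: list with `baseline`,
#'   `max_drop`, `min_time`, `persistence_days`.
#' @export
cooling_metrics <- function(sst, tc_passage_time, baseline_window = 6,
                            recovery_margin = 0.5) {
  stopifnot(inherits(sst, "box_series"))
  baseline <- series_baseline(sst, tc_passage_time, baseline_window)
  td <- time_days(sst$time)
  tp <- time_days(tc_passage_time)
  post <- which(td > tp & !is.na(sst$value))
  if (!length(post)) stop("no valid values after the passage time")
  vals <- sst$value[post]
  imin <- post[which.min(vals)]
  cold <- vals < baseline - recovery_margin
  # longest run of consecutive cold samples, in days at the series cadence
  cadence <- if (length(td) > 1) stats::median(diff(td)) else 1
  runs <- rle(cold)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  structure(list(baseline = baseline,
                 max_drop = max(0, baseline - min(vals)),
                 min_time = sst$time[imin],
                 persistence_days = longest * cadence),
            class = "cooling_metrics")
}

#' @export
print.cooling_metrics <- function(x, ...) {
  cat(sprintf(
    "<cooling_metrics> baseline %.2f degC, max drop %.2f degC, persistence %g days\n",
    x$baseline, x$max_drop, x$persistence_days))
  invisible(x)
}
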