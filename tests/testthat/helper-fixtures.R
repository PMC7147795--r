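# shared fixture builders (everything generated in code; no binary data)

# straight two-fix track heading north along a meridian
toy_track <- function(lat = c(10, 12), lon = c(70, 70),
                      msw = c(20, 20),
                      t0 = as.POSIXct("2017-12-01 00:00:00", tz = "UTC"),
                      step_h = 6) {
  tc_track(time = t0 + seq(0, by = step_h * 3600,
                           length.out = length(lat)),
           lat = lat, lon = lon, msw = msw)
}

# small tropical grid centred on (12N, 68E)
toy_grid <- function(half_deg = 2, by = 0.25) {
  geo_grid(seq(12 - half_deg, 12 + half_deg, by = by),
           seq(68 - half_deg, 68 + half_deg, by = by))
}

# uniform-stress vector series on a grid
uniform_stress <- function(grid, taux = 0.1, tauy = 0.05) {
  n <- c(length(grid$lats), length(grid$lons))
  vector_series(grid, matrix(taux, n[1], n[2]), matrix(tauy, n[1], n[2]),
                times = 1, varname = "tau", units = "N m-2")
}

# printed best-track table rows (lat, lon, MM/DD/HH, msw, printed TS);
# TS is NA at the first fix by convention
printed_track_ts <- function() {
  c(NA, 6.2, 4.9, 7.6, 6.0, 5.5, 4.8, 3.9, 4.6, 5.3, 3.7, 3.5, 2.9, 5.0,
    4.7, 4.0, 3.4, 3.2, 3.2, 5.1, 2.9, 5.2, 5.1, 5.1, 4.2, 3.6, 4.3)
}

# rows of the printed table whose TS is reproducible from the adjacent
# printed fixes by plain great-circle distance / elapsed time (1 d.p.);
# the remaining rows are presumed typos or smoothed upstream
self_consistent_rows <- function() c(9L, 11L, 16L, 17L, 18L, 19L, 20L, 27L)
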