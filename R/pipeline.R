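#' Bundled example best track
#'
#' The 6-hourly best track of the late-November 2017 Arabian Sea cyclone
#' (27 fixes, 29 Nov 06:00 UTC to 5 Dec 18:00 UTC) shipped with the package,
#' used as the default forcing for synthetic scenarios.
#'
#' @return A [tc_track()].
#' @export
example_track <- function() {
  parse_track(system.file("extdata", "besttrack_arabian_sea_2017.csv",
                          package = "tcbloom", mustWork = TRUE),
              year = 2017)
}

#' First local passage day of a cyclone over a box
#'
#' The earliest closest-approach day among the box's grid pixels, evaluated
#' on the given daily time grid — the reference time against which baselines,
#' bloom lags and cooling persistence are measured. Pure track/grid geometry;
#' no field data involved.
#'
#' @param track A [tc_track()].
#' @param grid A [geo_grid()].
#' @param box A [box_region()].
#' @param times Daily time vector overlapping the track's span.
#' @return A time (same representation as `times`).
#' @export
box_passage_time <- function(track, grid, box, times) {
  tca <- closest_approach_day(track, grid, times)
  idx <- box_index(grid, box)
  t0 <- min(tca[idx$ilat, idx$ilon])
  times[which.min(abs(as.numeric(times) - t0))]
}

#' Run a full synthetic bloom/cooling scenario end to end
#'
#' Generates cloud-masked chlorophyll and storm-cooled SST fields over a box
#' from a best track, runs the box-averaging pipeline, and returns the
#' recovered bloom and cooling metrics next to the injected ground truth.
#' This is the package's primary self-validation path: with known generator
#' parameters, the recovered lag, fold increase, cooling magnitude and
#' persistence can be compared against what was injected.
#'
#' @param scenario A [bloom_scenario()].
#' @param track A [tc_track()] (default [example_track()]).
#' @param box A [box_region()] (default the 11-14 degN, 67-70 degE study
#'   box).
#' @param resolution Grid spacing, degrees (default 0.25).
#' @param times Daily `Date` vector (default 2017-11-22 to 2017-12-30,
#'   covering pre-storm baseline through cooling recovery).
#' @param sst_drop,sst_duration_days Injected cooling magnitude (degC) and
#'   duration (days).
#' @param composite Use the two-day composite for the chlorophyll series
#'   (default FALSE: daily box means).
#' @return A list with elements `injected` (scenario parameters),
#'   `passage_time`, `bloom` (a [bloom_metrics()] result) and `cooling`
#'   (a [cooling_metrics()] result).
#' @examples
#' res <- run_bloom_scenario(bloom_scenario(lag_days = 4, seed = 7))
#' res$bloom$lag_days
#' @export
run_bloom_scenario <- function(scenario,
                               track = example_track(),
                               box = box_region(11, 14, 67, 70),
                               resolution = 0.25,
                               times = seq(as.Date("2017-11-22"),
                                           as.Date("2017-12-30"), by = 1),
                               sst_drop = 2, sst_duration_days = 10,
                               composite = FALSE) {
  stopifnot(inherits(scenario, "bloom_scenario"))
  grid <- geo_grid(seq(box$lat_min, box$lat_max, by = resolution),
                   seq(box$lon_min, box$lon_max, by = resolution))
  passage <- box_passage_time(track, grid, box, times)
  chl <- gen_bloom_fields(track, scenario, grid, times)
  sst <- gen_sst_field(track, grid, times, drop = sst_drop,
                       duration_days = sst_duration_days,
                       seed = scenario$seed + 1L)
  chl_series <- if (composite) two_day_composite(chl, box)
                else box_mean(chl, box)
  sst_series <- box_mean(sst, box)
  list(injected = list(scenario = scenario, sst_drop = sst_drop,
                       sst_duration_days = sst_duration_days),
       passage_time = passage,
       bloom = bloom_metrics(chl_series, passage),
       cooling = cooling_metrics(sst_series, passage))
}
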