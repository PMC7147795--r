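test_that("zero-amplitude vortex reduces to the background wind", {
  tr <- toy_track()
  g <- toy_grid()
  w <- gen_vortex_wind(tr, vortex_params(vmax = 0, rmax = 50,
                                         background_wind = c(3, -2)),
                       g, tr$time[1])
  expect_true(all(w$u == 3))
  expect_true(all(w$v == -2))
})

test_that("vortex peak wind sits at the radius of maximum wind", {
  # dense 1-km radial sweep of the tangential profile
  tr <- toy_track()
  params <- vortex_params(vmax = 42.5, rmax = 50)
  r_km <- seq(1, 300, by = 1)
  pts <- tcbloom:::vortex_wind_at(
    lat = rep(tr$lat[1], length(r_km)),
    lon = tr$lon[1] + r_km / (111.19 * cos(tr$lat[1] * pi / 180)),
    clat = tr$lat[1], clon = tr$lon[1], params = params, radius = 6.371e6)
  spd <- sqrt(pts$u^2 + pts$v^2)
  expect_equal(max(spd), 42.5, tolerance = 0.5 / 42.5)
  expect_equal(r_km[which.max(spd)], 50, tolerance = 0.03)
})

test_that("vortex wind is axisymmetric and cyclonic on a locally flat patch", {
  params <- vortex_params(vmax = 30, rmax = 40)
  r_deg <- 0.7
  # same radius, 90 degrees apart in azimuth about a near-equatorial centre
  east <- tcbloom:::vortex_wind_at(0, 100 + r_deg, 0, 100, params, 6.371e6)
  north <- tcbloom:::vortex_wind_at(r_deg, 100, 0, 100, params, 6.371e6)
  expect_equal(sqrt(east$u^2 + east$v^2), sqrt(north$u^2 + north$v^2),
               tolerance = 1e-9)
  expect_gt(east$v, 0)  # counterclockwise: northward on the east side
  expect_lt(north$u, 0) # westward on the north side
})

test_that("vortex generator enforces the track time span", {
  tr <- toy_track()
  g <- toy_grid()
  expect_error(gen_vortex_wind(tr, vortex_params(20, 50), g,
                               tr$time[1] - 3600), "span")
})

test_that("empty eddy list gives quiescent ocean; negative eddy is cyclonic", {
  g <- toy_grid()
  calm <- gen_eddy_ssh_currents(list(), g)
  expect_true(all(calm$ssh$data == 0))
  expect_true(all(calm$currents$u == 0))
  one <- gen_eddy_ssh_currents(list(eddy_spec(c(12, 68), -0.1, 60)), g)
  ic <- which(g$lats == 12); jc <- which(g$lons == 68)
  expect_equal(which.min(one$ssh$data[, , 1]),
               (jc - 1L) * length(g$lats) + ic) # SSH minimum at the centre
  vort <- relative_vorticity(one$currents)
  expect_gt(vort[ic, jc, 1, 1], 0) # cyclonic core
  # counterclockwise circulation: northward east of centre
  expect_gt(one$currents$v[ic, jc + 4L, 1, 1], 0)
})

test_that("multi-eddy SSH superposes linearly to 1e-12", {
  g <- toy_grid()
  e1 <- eddy_spec(c(11.5, 67.5), -0.1, 50)
  e2 <- eddy_spec(c(12.5, 68.5), -0.05, 80)
  both <- gen_eddy_ssh_currents(list(e1, e2), g)
  s1 <- gen_eddy_ssh_currents(list(e1), g)
  s2 <- gen_eddy_ssh_currents(list(e2), g)
  expect_lt(max(abs(both$ssh$data - s1$ssh$data - s2$ssh$data)), 1e-12)
})

test_that("geostrophy is refused on grids touching the equatorial band", {
  g_eq <- geo_grid(seq(-1, 3, 0.5), seq(67, 70, 0.5))
  expect_error(gen_eddy_ssh_currents(list(eddy_spec(c(1, 68), -0.1, 50)), g_eq),
               "equator")
})

test_that("synthetic profile puts the N maximum at the prescribed thermocline", {
  depths <- seq(0, 200, by = 1)
  p <- gen_profile(stratification_params(thermocline_depth = 46.2,
                                         thermocline_width = 10), depths)
  expect_equal(p$temp[1], 29) # normalised so T(0) = sst exactly
  np <- buoyancy_frequency(p)
  expect_equal(thermocline_depth(np), 46.2, tolerance = 1 / 46.2)
})

test_that("uniform-water profile is unstratified", {
  p <- gen_profile(stratification_params(sst = 15, deep_t = 15,
                                         sss = 35, deep_s = 35),
                   seq(0, 100, 2))
  np <- buoyancy_frequency(p)
  expect_true(all(np$n == 0))
})

test_that("doubling the thermocline width halves the peak N^2", {
  depths <- seq(0, 300, by = 0.5)
  n2max <- function(w) {
    p <- gen_profile(stratification_params(thermocline_depth = 80,
                                           thermocline_width = w), depths)
    max(buoyancy_frequency(p)$n2)
  }
  expect_equal(n2max(20) / n2max(10), 0.5, tolerance = 0.05)
})

test_that("bloom peaks exactly lag_days after local closest approach", {
  tr <- example_track()
  g <- toy_grid(half_deg = 1.5)
  days <- seq(as.Date("2017-11-25"), as.Date("2017-12-20"), by = 1)
  sc <- bloom_scenario(baseline_chl = 0.3, peak_chl = 3, lag_days = 4,
                       cloud_fraction = 0, seed = 1)
  chl <- gen_bloom_fields(tr, sc, g, days)
  tca <- attr(chl, "tca")
  day_num <- as.numeric(days)
  argmax_day <- apply(chl$data, c(1, 2), function(v) day_num[which.max(v)])
  expect_true(all(argmax_day - tca == 4))
})

test_that("flat scenario stays at baseline and full mask fraction obeys the law of large numbers", {
  tr <- example_track()
  g <- toy_grid(half_deg = 1.5)
  days <- seq(as.Date("2017-11-28"), as.Date("2017-12-10"), by = 1)
  flat <- gen_bloom_fields(tr, bloom_scenario(baseline_chl = 0.2,
                                              peak_chl = 0.2, lag_days = 3,
                                              cloud_fraction = 0, seed = 1),
                           g, days)
  expect_true(all(flat$data == 0.2))
  # >= 1e5 pixel-days for the 1% binomial bound
  gbig <- geo_grid(seq(5, 19.75, 0.25), seq(55, 79.75, 0.25))
  days2 <- seq(as.Date("2017-11-29"), as.Date("2017-12-18"), by = 1)
  masked <- gen_bloom_fields(tr, bloom_scenario(cloud_fraction = 0.3,
                                                seed = 99), gbig, days2)
  expect_gte(length(masked$data), 1e5)
  expect_equal(mean(is.na(masked$data)), 0.3, tolerance = 0.01 / 0.3)
})

test_that("generators are bit-identical under a fixed seed and leave the RNG alone", {
  tr <- example_track()
  g <- toy_grid()
  days <- seq(as.Date("2017-11-28"), as.Date("2017-12-12"), by = 1)
  sc <- bloom_scenario(cloud_fraction = 0.4, seed = 7)
  set.seed(123); probe_before <- runif(3)
  set.seed(123)
  a <- gen_bloom_fields(tr, sc, g, days)
  b <- gen_bloom_fields(tr, sc, g, days)
  probe_after <- runif(3)
  expect_identical(a$data, b$data)
  expect_identical(probe_before, probe_after) # global RNG state untouched
  s1 <- gen_sst_field(tr, g, days, seed = 11)
  s2 <- gen_sst_field(tr, g, days, seed = 11)
  expect_identical(s1$data, s2$data)
})

test_that("SST generator injects the requested step anomaly", {
  tr <- example_track()
  g <- toy_grid()
  days <- seq(as.Date("2017-11-25"), as.Date("2017-12-25"), by = 1)
  sst <- gen_sst_field(tr, g, days, baseline = 29, drop = 2.5,
                       duration_days = 8, noise_sd = 0, seed = 1)
  tca <- attr(sst, "tca")
  dn <- as.numeric(days)
  px <- sst$data[3, 3, ]
  cooled <- which(px < 29)
  expect_equal(length(cooled), 8L)
  expect_equal(dn[cooled[1]] - tca[3, 3], 1) # one-day onset lag
  expect_true(all(px[cooled] == 29 - 2.5))
})

test_that("pulse generator places its extremum at closest approach", {
  tr <- example_track()
  g <- toy_grid()
  days <- seq(as.Date("2017-11-25"), as.Date("2017-12-15"), by = 1)
  par <- gen_pulse_field(tr, g, days, base = 45, amplitude = -25,
                         width_days = 1.5, varname = "par")
  tca <- attr(gen_sst_field(tr, g, days, noise_sd = 0), "tca")
  dn <- as.numeric(days)
  imin <- which.min(par$data[5, 5, ])
  expect_equal(dn[imin], tca[5, 5])
  expect_equal(max(par$data), 45, tolerance = 1e-6)
})
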