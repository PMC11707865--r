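test_that("generated tables are reproducible under a fixed master seed", {
  sc <- lake_scenario(n_fish = 2, seed = 123)
  g <- gen_bathymetry(sc)
  p1 <- gen_profiles(sc, 2017)
  p2 <- gen_profiles(sc, 2017)
  expect_identical(p1, p2)
  s1 <- gen_stations(sc, g)
  s2 <- gen_stations(sc, g)
  expect_identical(s1, s2)
  daily <- aggregate_daily_profiles(p1, n_strata = 25)
  hab <- daily_habitat_volumes(daily, compute_hypsographic_curve(g))
  t1 <- gen_tracks(sc, g, hab, 2017, months = 6)
  t2 <- gen_tracks(sc, g, hab, 2017, months = 6)
  expect_identical(t1, t2)
  d1 <- gen_detections(sc, t1, s1)
  d2 <- gen_detections(sc, t2, s2)
  expect_identical(d1, d2)
})

test_that("basin shape limits behave as advertised", {
  # very large exponent: flat-bottomed cylinder, near-constant areas
  cyl <- compute_hypsographic_curve(
    gen_bathymetry(lake_scenario(bowl_exponent = 60, cell_size = 25)))
  expect_gt(min(cyl$area_top_m2[1:24]) / max(cyl$area_top_m2[1:24]), 0.9)
  # paraboloid strata match the analytic hypsograph within 2%
  sc <- lake_scenario(bowl_exponent = 2, cell_size = 25)
  cv <- compute_hypsographic_curve(gen_bathymetry(sc))
  R <- sqrt(sc$surface_area_km2 * 1e6 / pi)
  analytic <- vapply(seq_len(nrow(cv)), function(i) {
    (bowl_area(i - 1, R, 25, 2) + bowl_area(i, R, 25, 2)) / 2
  }, numeric(1))
  expect_lt(max(abs(cv$volume_m3 - analytic) / analytic[1]), 0.02)
  expect_lt(abs(total_volume(cv) / bowl_volume(R, 25, 2) - 1), 0.02)
  # the deepest stratum index equals the maximum depth
  expect_equal(max(cv$stratum), 25L)
  expect_error(gen_bathymetry(lake_scenario(bowl_exponent = -1)), "degenerate")
})

test_that("profiles depict stratification with hypolimnetic oxygen depletion", {
  sc <- lake_scenario(seed = 31)
  pr <- gen_profiles(sc, 2017)
  daily <- aggregate_daily_profiles(pr, n_strata = 25)
  truth <- attr(pr, "truth")
  # bottom water goes hypoxic by late summer
  aug <- daily[daily$stratum == 24 &
                 format(daily$date, "%m-%d") == "08-20", ]
  expect_lt(aug$do_mgl, 3)
  # a mid-summer day has optimum strata (18-23 C and DO > 5)
  jul <- daily[format(daily$date, "%m-%d") == "07-15", ]
  lab <- classify_habitat(jul$temp_c, jul$do_mgl)
  expect_true("optimum" %in% lab)
  # hypoxic volume is non-decreasing through the stratified period,
  # then collapses to zero at turnover
  cv <- compute_hypsographic_curve(gen_bathymetry(sc))
  hab <- daily_habitat_volumes(daily, cv)
  doy <- as.integer(format(hab$date, "%j"))
  strat <- doy >= truth$onset & doy < truth$turnover
  hv <- hab$volume_hypoxic[strat]
  expect_true(all(diff(hv) >= -1e-6))
  expect_true(all(hab$volume_hypoxic[doy >= truth$turnover] == 0))
  # zero depletion rate: no hypoxia at any time
  pr0 <- gen_profiles(lake_scenario(do_depletion = 0), 2017)
  d0 <- aggregate_daily_profiles(pr0, n_strata = 25)
  h0 <- daily_habitat_volumes(d0, cv)
  expect_true(all(h0$volume_hypoxic == 0))
})

test_that("habitat-neutral coefficients give stationary movement", {
  sc <- lake_scenario(n_fish = 3, step_b = 0, step_c = 0, seed = 77)
  sim <- simulate_study(sc, months = 5:9)
  tr <- sim$tracks$truth
  monthly <- tapply(tr$true_path_km, tr$month, mean)
  expect_lt(max(monthly) / min(monthly), 1.25)
  expect_false(any(tr$emigrated))  # suitable floor never triggered
})

test_that("movement tracks respond to habitat compression", {
  sim <- shared_sim()
  sc <- sim$scenario
  tr <- sim$tracks$truth
  hab <- sim$habitat
  mo <- as.integer(format(hab$date, "%m"))
  keep <- mo %in% 6:8
  # the generator's expected step modifier per month
  nonhyp <- hab$prop_suitable[keep] + hab$prop_optimum[keep]
  modifier <- (sc$step_a + sc$step_b * hab$prop_optimum[keep]) *
    nonhyp^sc$step_c
  mod_m <- tapply(modifier, mo[keep], mean)
  path <- tapply(tr$true_path_km, tr$month, mean)[names(mod_m)]
  # the most compressed month yields the shortest true paths
  expect_equal(unname(which.min(mod_m)), unname(which.min(path)))
  expect_gt(path[which.max(mod_m)], path[which.min(mod_m)])
  # all positions stay inside the water mask
  mask <- water_mask(sim$grid, min_depth = 1)
  pos <- sim$tracks$positions
  rc <- oxytel:::xy_cell(mask, pos$x, pos$y)
  expect_true(all(mask[rc]))
})

test_that("the detection model is logistic around the 50% range", {
  sc <- lake_scenario(seed = 55, fp_rate = 0)
  st <- data.frame(station_id = "S01", x = 0, y = 0,
                   range_iso_m = 400, range_strat_m = 280)
  t0 <- as.POSIXct("2017-11-01 00:00:00", tz = "UTC")  # isothermal season
  hold <- function(x) list(positions = data.frame(
    transmitter_id = "F01", time = t0 + seq(0, 86400 * 4, 600), x = x, y = 0))
  at_r50 <- gen_detections(sc, hold(400), st)
  n_tx <- attr(at_r50, "n_transmissions")
  expect_equal(nrow(at_r50) / n_tx, 0.5, tolerance = 0.05)
  at_zero <- gen_detections(sc, hold(0), st)
  expect_gt(nrow(at_zero) / attr(at_zero, "n_transmissions"), 0.99)
  at_far <- gen_detections(sc, hold(2000), st)
  expect_equal(nrow(at_far), 0L)
})

test_that("injected spurious singletons are caught by the QC filter", {
  sim <- shared_sim()
  fp <- attr(sim$detections, "injected_fp")
  expect_gt(nrow(fp), 20)  # enough injected noise to measure removal
  kept <- filter_false_positives(sim$detections,
                                 qc_config(nominal_delay = sim$scenario$tag_delay))
  key <- function(d) paste(round(as.numeric(d$detection_timestamp_utc), 3),
                           d$transmitter_id, d$receiver_sn)
  surviving <- sum(key(fp) %in% key(kept))
  expect_lte(surviving / nrow(fp), 0.05)
})
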