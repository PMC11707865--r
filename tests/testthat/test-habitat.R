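test_that("classification applies the DO and temperature thresholds", {
  th <- habitat_thresholds()
  expect_equal(classify_habitat(20, 6, th), "optimum")
  expect_equal(classify_habitat(20, 2, th), "hypoxic")
  expect_equal(classify_habitat(25, 8, th), "suitable")  # too warm
  # boundaries: DO thresholds strict, temperature band inclusive
  expect_equal(classify_habitat(20, 3, th), "suitable")
  expect_equal(classify_habitat(20, 5, th), "suitable")
  expect_equal(classify_habitat(c(18, 23), c(6, 6), th),
               c("optimum", "optimum"))
  expect_error(classify_habitat(NaN, 5, th), "finite")
  expect_error(habitat_thresholds(hypoxia_do = 6, optimum_do = 5), "below")
})

test_that("daily aggregation averages casts, interpolates and extrapolates", {
  # two casts at 10 m: the daily value is their mean
  p <- rbind(make_profile("2017-06-01", temp = 15, do = 4, depths = 10),
             make_profile("2017-06-01", temp = 15, do = 6, depths = 10))
  d <- aggregate_daily_profiles(p, n_strata = 12)
  expect_equal(d$do_mgl[d$stratum == 10], 5)
  # readings at 1 and 3 m only: stratum 2 is the midpoint
  p2 <- make_profile("2017-06-02", temp = c(20, 10), do = c(8, 4),
                     depths = c(1, 3))
  d2 <- aggregate_daily_profiles(p2, n_strata = 3)
  expect_equal(d2$temp_c[d2$stratum == 2], 15)
  expect_equal(d2$do_mgl[d2$stratum == 2], 6)
  expect_true(d2$filled[d2$stratum == 2])
  # readings only above 5 m in a 24-m column: deeper strata copy the 5-m value
  p3 <- make_profile("2017-06-03", temp = c(22, 21, 20, 19, 18),
                     do = c(9, 9, 8, 8, 7), depths = 1:5)
  d3 <- aggregate_daily_profiles(p3, n_strata = 24)
  expect_true(all(d3$temp_c[d3$stratum >= 5] == 18))
  expect_true(all(d3$do_mgl[d3$stratum >= 5] == 7))
  expect_true(all(d3$filled[d3$stratum > 5]))
})

test_that("daily volumes accrue stratum volumes to labels and partition the lake", {
  bed <- matrix(73, 2, 5)  # 2 m deep; two 50 m3 strata with 5 cells of 5x5...
  g <- bathymetry_grid(matrix(73, 2, 1), cell_size = sqrt(50), surface_elevation = 75)
  cv <- compute_hypsographic_curve(g)
  expect_equal(cv$volume_m3, c(100, 100))
  d <- data.frame(date = as.Date("2017-07-01"), stratum = 1:2,
                  temp_c = c(20, 20), do_mgl = c(6, 1))  # optimum over hypoxic
  hv <- daily_habitat_volumes(d, cv)
  expect_equal(hv$volume_optimum, 100)
  expect_equal(hv$volume_hypoxic, 100)
  expect_equal(hv$volume_suitable, 0)
  # all-suitable day fills the lake
  d2 <- transform(d, temp_c = c(10, 10), do_mgl = c(6, 6))
  hv2 <- daily_habitat_volumes(d2, cv)
  expect_equal(hv2$volume_suitable, total_volume(cv))
  expect_equal(hv2$prop_suitable, 1)
})

test_that("partition identity holds on the synthetic lake, every day", {
  sim <- shared_sim()
  tot <- total_volume(sim$curve)
  sums <- with(sim$habitat, volume_hypoxic + volume_suitable + volume_optimum)
  expect_equal(sums, rep(tot, nrow(sim$habitat)))
  props <- with(sim$habitat, prop_hypoxic + prop_suitable + prop_optimum)
  expect_true(all(abs(props - 1) < 1e-9))
})

test_that("raising the hypoxia threshold never shrinks hypoxic volume", {
  sim <- shared_sim()
  v3 <- daily_habitat_volumes(sim$daily, sim$curve,
                              habitat_thresholds(hypoxia_do = 3))
  v4 <- daily_habitat_volumes(sim$daily, sim$curve,
                              habitat_thresholds(hypoxia_do = 4))
  expect_true(all(v4$volume_hypoxic >= v3$volume_hypoxic))
})

test_that("widening optimum to all non-hypoxic water empties the suitable class", {
  sim <- shared_sim()
  th <- habitat_thresholds(hypoxia_do = 3, optimum_do = 3 + 1e-9,
                           optimum_temp = c(-100, 100))
  v <- daily_habitat_volumes(sim$daily, sim$curve, th)
  expect_true(all(v$volume_suitable < 1e-6 * total_volume(sim$curve)))
})

test_that("monthly means average the available days and flag thin coverage", {
  dates <- seq(as.Date("2017-06-01"), as.Date("2017-06-30"), by = "day")
  hyp <- rep(c(0, 10e6), 15)
  s <- structure(data.frame(date = dates, volume_hypoxic = hyp,
                            volume_suitable = 20e6 - hyp, volume_optimum = 0),
                 class = c("habitat_volume_series", "data.frame"))
  m <- monthly_mean_volumes(s)
  expect_equal(m$volume_hypoxic, 5e6)
  expect_equal(m$n_days, 30L)
  expect_false(m$low_coverage)
  s1 <- s[1, ]
  expect_warning(m1 <- monthly_mean_volumes(s1), "fewer than")
  expect_true(m1$low_coverage)
  expect_equal(m1$volume_hypoxic, s1$volume_hypoxic)
})

test_that("the seasonal window spans 129 days regardless of leap years", {
  expect_equal(season_window()$n_days, 129L)
  # both endpoints are after February: the count is leap-invariant
  n2016 <- as.integer(as.Date("2016-10-02") - as.Date("2016-05-27")) + 1L
  expect_equal(n2016, 129L)
})

test_that("seasonal summary computes cumulative and daily proportions", {
  win <- season_window()
  dates <- seq(as.Date("2017-05-27"), as.Date("2017-10-02"), by = "day")
  expect_equal(length(dates), win$n_days)
  tot <- 283e6
  V <- 30e6
  s <- data.frame(date = dates, volume_hypoxic = V,
                  volume_suitable = tot - V, volume_optimum = 0)
  out <- seasonal_summary(s, total_volume = tot)
  hyp <- out[out$category == "hypoxic", ]
  expect_equal(hyp$cumulative_proportion, V / tot)
  expect_equal(hyp$daily_min, V / tot)
  expect_equal(hyp$daily_max, V / tot)
  # zero hypoxia: hypoxic cumulative 0, suitable + optimum = 1
  s2 <- data.frame(date = dates, volume_hypoxic = 0,
                   volume_suitable = tot / 2, volume_optimum = tot / 2)
  out2 <- seasonal_summary(s2, total_volume = tot)
  expect_equal(out2$cumulative_proportion[out2$category == "hypoxic"], 0)
  expect_equal(sum(out2$cumulative_proportion), 1)
  # strict mode rescales by the observed day count
  s3 <- s[1:100, ]
  lax <- seasonal_summary(s3, total_volume = tot, strict = FALSE)
  expect_equal(lax$cumulative_proportion[lax$category == "hypoxic"],
               100 * V / (win$n_days * tot))
  strict <- seasonal_summary(s3, total_volume = tot, strict = TRUE)
  expect_equal(strict$cumulative_proportion[strict$category == "hypoxic"],
               V / tot)
})
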