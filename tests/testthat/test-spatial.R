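# build a water_mask from a logical matrix (TRUE = water)
toy_mask <- function(m, cs = 100) {
  bed <- ifelse(m, 70, NA_real_)
  water_mask(bathymetry_grid(bed, cell_size = cs, surface_elevation = 75))
}
# station table at cell centres
st_at <- function(mask, ids, rows, cols) {
  xy <- oxytel:::cell_xy(mask, rows, cols)
  data.frame(station_id = ids, x = xy[, 1], y = xy[, 2])
}

test_that("open-water least-cost distance equals the straight path", {
  mask <- toy_mask(matrix(TRUE, 12, 12), cs = 100)
  st <- st_at(mask, c("A", "B"), c(6, 6), c(1, 11))
  d <- least_cost_distances(mask, st)
  expect_equal(d["A", "B"], 1000)
  expect_equal(d["A", "A"], 0)
  expect_equal(d, t(d))
})

test_that("walls force detours matching a brute-force Dijkstra oracle", {
  m <- matrix(TRUE, 9, 9)
  m[2:9, 5] <- FALSE  # wall with a gap at the top row
  mask <- toy_mask(m, cs = 50)
  st <- st_at(mask, c("A", "B"), c(8, 8), c(2, 8))
  d <- least_cost_distances(mask, st)
  oracle <- brute_dijkstra(m, 50, c(8, 2), c(8, 8))
  expect_equal(d["A", "B"], oracle)
  expect_gt(d["A", "B"], 50 * 6)  # strictly longer than the blocked beeline
})

test_that("least-cost distances match the oracle on random masks", {
  set.seed(42)
  for (rep in 1:6) {
    m <- matrix(runif(15 * 15) > 0.25, 15, 15)
    m[8, 8] <- TRUE; m[2, 2] <- TRUE
    mask <- toy_mask(m, cs = 10)
    oracle <- brute_dijkstra(m, 10, c(2, 2), c(8, 8))
    if (!is.finite(oracle)) next
    st <- st_at(mask, c("A", "B"), c(2, 8), c(2, 8))
    d <- least_cost_distances(mask, st, tolerance = 0)
    expect_equal(d["A", "B"], oracle)
  }
})

test_that("snapping tolerates nearby land but rejects distant stations", {
  m <- matrix(TRUE, 10, 10); m[1:5, 1:5] <- FALSE
  mask <- toy_mask(m, cs = 100)
  # station 2 cells into the land corner snaps to water
  st <- data.frame(station_id = "A", x = 350, y = 650)
  snapped <- snap_stations(mask, st, tolerance = 3)
  expect_true(mask[snapped$row, snapped$col])
  # far into the land corner: data error
  far <- data.frame(station_id = "B", x = 50, y = 950)
  expect_error(snap_stations(mask, far, tolerance = 3), "snap tolerance")
})

test_that("disconnected basins are reported, not silently bridged", {
  m <- matrix(TRUE, 7, 7)
  m[, 4] <- FALSE  # impassable wall
  mask <- toy_mask(m)
  st <- st_at(mask, c("A", "B"), c(4, 4), c(2, 6))
  expect_error(least_cost_distances(mask, st), "disconnected")
})

test_that("distances satisfy the triangle inequality and the octile bound", {
  mask <- toy_mask(matrix(TRUE, 15, 15), cs = 100)
  set.seed(9)
  rows <- sample(15, 5); cols <- sample(15, 5)
  st <- st_at(mask, LETTERS[1:5], rows, cols)
  d <- least_cost_distances(mask, st)
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-9)
  # on an all-water mask the path is octile: within 8.25% of Euclidean
  # plus one diagonal cell of discretisation
  eu <- as.matrix(dist(st[, c("x", "y")]))
  expect_true(all(d >= eu - 1e-9))
  expect_true(all(d <= 1.0824 * eu + 100 * sqrt(2) + 1e-9))
})

test_that("adjustment factors follow the summed-radius ratio", {
  rg <- data.frame(station_id = c("A", "B", "C"),
                   range_iso_m = c(400, 300, 200),
                   range_strat_m = c(200, 150, 200))
  expect_equal(adjustment_factor(rg, "A", "B", "isothermal"), 1)
  expect_equal(adjustment_factor(rg, "A", "B", "stratified"), 2)  # both halved
  expect_equal(adjustment_factor(rg, "C", "C", "stratified"), 1)  # unchanged
  expect_equal(adjustment_factor(rg, "A", "C", "stratified"),
               (400 + 200) / (200 + 200))
  # monotone: shrinking a state range never lowers the factor
  rg2 <- rg; rg2$range_strat_m[1] <- 100
  expect_gt(adjustment_factor(rg2, "A", "B", "stratified"),
            adjustment_factor(rg, "A", "B", "stratified"))
  expect_error(adjustment_factor(transform(rg, range_strat_m = 0),
                                 "A", "B", "stratified"), "positive")
  # clamping is applied and reported
  rg3 <- data.frame(station_id = c("A", "B"), range_iso_m = c(1000, 1000),
                    range_strat_m = c(50, 50))
  expect_warning(f <- adjustment_factor(rg3, "A", "B", "stratified"), "clamped")
  expect_equal(f, 5)
  # a custom factor strategy can be plugged in
  f1 <- adjustment_factor(rg, "A", "B", "stratified",
                          factor_fun = function(ia, ib, sa, sb) rep(1, length(ia)))
  expect_equal(f1, 1)
})

test_that("the synthetic array's mean stratified factor matches the disc-area oracle", {
  sim <- shared_sim()
  pairs <- station_pairs(water_mask(sim$grid, min_depth = 1), sim$stations)
  # stratified discs cover ~55.7% of isothermal area, so the factor
  # should sit near 1 / sqrt(0.557)
  expect_equal(mean(pairs$factor_stratified), 1 / sqrt(0.557), tolerance = 0.02)
  expect_true(all(pairs$factor_isothermal == 1))
})

test_that("stratification state is classified from the temperature difference", {
  uniform <- data.frame(date = as.Date("2017-11-10") + 0:9,
                        stratum = rep(1:24, each = 10)[1:240],
                        temp_c = 10, do_mgl = 9)
  uniform <- do.call(rbind, lapply(0:9, function(d)
    data.frame(date = as.Date("2017-11-10") + d, stratum = 1:24,
               temp_c = 10, do_mgl = 9)))
  s <- classify_stratification_state(uniform)
  expect_equal(s$state, "isothermal")
  strat <- transform(uniform, temp_c = ifelse(stratum < 10, 24, 10))
  s2 <- classify_stratification_state(strat)
  expect_equal(s2$state, "stratified")
  # simulator ground truth: July stratified, November isothermal
  sim <- shared_sim()
  st <- sim$states
  expect_equal(st$state[st$month == 7], "stratified")
  expect_equal(st$state[st$month == 11], "isothermal")
  expect_error(classify_stratification_state(uniform[0, ]), "no profile")
})
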