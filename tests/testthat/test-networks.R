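test_that("edge weights count station-changing transitions", {
  net <- build_network(make_detections(c("A", "A", "B", "A")))
  expect_equal(net$edges$weight, 2L)
  expect_equal(net$edges$station_a, "A")
  expect_equal(net$edges$station_b, "B")
  # all detections at one station: no edges
  expect_equal(nrow(build_network(make_detections(rep("A", 5)))$edges), 0L)
  # a tour visits three pairs once each
  tour <- build_network(make_detections(c("A", "B", "C", "A")))
  expect_equal(nrow(tour$edges), 3L)
  expect_true(all(tour$edges$weight == 1L))
  # fewer than two detections: empty, flagged
  single <- build_network(make_detections("A"))
  expect_true(single$empty)
  expect_equal(single$n_moves, 0L)
})

test_that("total edge weight equals the number of moves (conservation)", {
  set.seed(3)
  for (rep in 1:10) {
    visits <- sample(LETTERS[1:5], 40, replace = TRUE)
    net <- build_network(make_detections(visits))
    expect_equal(sum(net$edges$weight), sum(visits[-1] != visits[-40]))
    expect_equal(net$n_moves, sum(net$edges$weight))
    # no self-edges, positive integer weights
    expect_true(all(net$edges$station_a != net$edges$station_b))
    expect_true(all(net$edges$weight >= 1L))
  }
})

test_that("displacement distance is the weighted factor-adjusted path sum", {
  pairs <- data.frame(station_a = c("A", "A", "B"),
                      station_b = c("B", "C", "C"),
                      least_cost_m = c(2000, 1500, 1000),
                      factor_isothermal = 1,
                      factor_stratified = c(1.5, 2, 1.2))
  net <- build_network(make_detections(c("A", "B", "A", "B")))  # A-B x3
  iso <- displacement_distance(net, pairs, "isothermal")
  expect_equal(iso$displacement_km, 3 * 1 * 2)
  strat <- displacement_distance(net, pairs, "stratified")
  expect_equal(strat$displacement_km, 3 * 1.5 * 2)
  # multi-edge network equals the hand-summed enumeration oracle
  net2 <- build_network(make_detections(c("A", "B", "C", "A", "C", "B")))
  for (st in c("isothermal", "stratified")) {
    fcol <- paste0("factor_", st)
    expect_equal(displacement_distance(net2, pairs, st)$displacement_km,
                 sum_displacement(net2$edges, pairs, fcol))
  }
  # linearity in weights: doubling the sequence doubles the distance
  net3 <- build_network(make_detections(rep(c("A", "B"), 7)))  # A-B x13
  expect_equal(displacement_distance(net3, pairs, "isothermal")$displacement_km,
               13 / 3 * iso$displacement_km)
  # a missing pair entry is a named error
  netx <- build_network(make_detections(c("A", "D", "A")))
  expect_error(displacement_distance(netx, pairs, "isothermal"), "A-D")
})

test_that("patterned commutes are flagged against the shuffled null", {
  # strict alternation over four stations: far fewer distinct edges than
  # a random reordering of the same visits
  visits <- rep(c("A", "B", "C", "D"), 10)
  net <- build_network(make_detections(visits))
  sig <- random_network_test(net, n_perm = 1000, alpha = 0.05, seed = 1)
  expect_true(sig$significant)
  expect_lte(sig$p_value, 0.05)
  expect_equal(sig$observed, 4)
  # degenerate single-station sequence: undefined test, dropped
  deg <- build_network(make_detections(rep("A", 6)))
  sdeg <- random_network_test(deg, n_perm = 100)
  expect_true(is.na(sdeg$p_value))
  expect_false(sdeg$significant)
})

test_that("permutation p-values are valid under the iid-visits null", {
  # small replicate check; the full calibration runs in the acceptance suite
  set.seed(21)
  pv <- replicate(50, {
    net <- build_network(make_detections(sample(LETTERS[1:6], 40, replace = TRUE)))
    random_network_test(net, n_perm = 99)$p_value
  })
  expect_lte(mean(pv <= 0.05), 0.12)
  expect_gt(mean(pv), 0.3)  # p-values not collapsed toward 0
})

test_that("path weights pool across networks by month and edge", {
  n1 <- build_network(make_detections(c("A", "B", "A")), month = 6, year = 2017)
  n2 <- build_network(make_detections(c("A", "B", "A", "B")), month = 6,
                      year = 2018)
  n3 <- build_network(make_detections(c("C", "D")), month = 7, year = 2017)
  pooled <- export_path_weights(list(n1, n2, n3))
  ab <- pooled[pooled$station_a == "A" & pooled$month == 6, ]
  expect_equal(ab$weight, 2L + 3L)
  expect_equal(nrow(pooled), 2L)  # disjoint edges union
  expect_equal(nrow(export_path_weights(list())), 0L)
  st <- data.frame(station_id = c("A", "B", "C", "D"), x = 1:4, y = 4:1)
  with_xy <- export_path_weights(list(n1, n3), stations = st)
  expect_equal(with_xy$xa, c(1, 3))
})

test_that("the movement driver wires QC, residency, pairs and states together", {
  t0 <- as.POSIXct("2017-06-01 00:00:00", tz = "UTC")
  # two fish pinging all month between A and B (high residency)
  mk <- function(id, stations) {
    data.frame(detection_timestamp_utc = t0 + seq(0, 29.5 * 86400, 3600),
               transmitter_id = id,
               receiver_sn = rep(stations, length.out = 709))
  }
  det <- rbind(mk("F1", c("A", "B")), mk("F2", c("A", "B", "C")))
  roster <- data.frame(transmitter_id = c("F1", "F2"))
  res <- residency(det, roster)
  eligible <- residency_filter(res$fish)
  pairs <- data.frame(station_a = c("A", "A", "B"), station_b = c("B", "C", "C"),
                      least_cost_m = 1000, factor_isothermal = 1,
                      factor_stratified = 1.4)
  states <- data.frame(year = 2017, month = 6, state = "stratified")
  mv <- movement_analysis(det, eligible, pairs, states, months = 6,
                          n_perm = 99, seed = 4)
  expect_equal(length(mv$networks), 2L)
  expect_equal(nrow(mv$significance), 2L)
  # F1 commutes strictly: significant, displacement = moves * 1.4 * 1 km
  f1 <- mv$displacement[mv$displacement$transmitter_id == "F1", ]
  if (nrow(f1)) expect_equal(f1$displacement_km, 708 * 1.4 * 1)
  expect_true(all(mv$displacement$state == "stratified"))
})
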