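#' Synthetic lake and telemetry scenario
#'
#' Parameter bundle for the built-in simulator: a bowl-shaped stratifying
#' basin, a seasonal oxythermal cycle with hypolimnetic oxygen depletion, a
#' fixed receiver array whose detection ranges shrink under stratification,
#' and tagged fish whose movement scales with habitat availability. Defaults
#' emulate a ~25-m deep, ~21-km^2 urban embayment with a 21-receiver array
#' and 120-s tags: stratification from late May to early October, epilimnion
#' peaking near 25 C, hypolimnetic DO depleting at 0.12 mg/L/day, and
#' stratified 50% detection ranges whose disc area is ~56% of the isothermal
#' coverage.
#'
#' @param max_depth maximum depth, m.
#' @param surface_area_km2 target lake surface area, km^2.
#' @param bowl_exponent radial depth profile exponent `p` in
#'   `depth = max_depth * (1 - (rho/rho_max)^p)`; 1 = cone, 2 = paraboloid.
#'   The default 2.2 gives a mean depth near 13 m.
#' @param cell_size raster resolution, m.
#' @param surface_elevation water surface above datum, m.
#' @param onset_day,turnover_day day-of-year bounds of the stratified period.
#' @param epi_temp_peak epilimnion temperature peak, C (at `peak_day`).
#' @param peak_day day-of-year of the temperature peak.
#' @param thermocline_start initial thermocline depth at onset, m.
#' @param thermocline_rate thermocline deepening rate, m/day.
#' @param do_depletion hypolimnetic DO depletion rate, mg/L/day.
#' @param n_stations number of receiver stations.
#' @param range_iso_m,range_strat_m mean 50%-detection radii, m.
#' @param range_jitter relative station-to-station range variation.
#' @param n_fish number of tagged fish.
#' @param tag_delay,tag_jitter nominal transmission delay and uniform jitter
#'   half-width, s.
#' @param time_step track time step, s.
#' @param step_scale base expected step length, m per time step.
#' @param step_a,step_b,step_c habitat response of the expected step length:
#'   `step_scale * (step_a + step_b * optimum_prop) * suitable_prop^step_c`.
#' @param turn_sd turning-angle standard deviation, radians.
#' @param emigration_floor suitable-habitat proportion below which fish may
#'   leave the array.
#' @param emigration_prob daily emigration probability once below the floor.
#' @param fp_rate expected spurious singleton detections per station per day
#'   (false positives injected for QC testing).
#' @param seed master seed; every derived random stream is spawned from it so
#'   a fixed seed reproduces every generated table exactly.
#' @return An object of class `lake_scenario`.
#' @export
lake_scenario <- function(max_depth = 25, surface_area_km2 = 21,
                          bowl_exponent = 2.2, cell_size = 50,
                          surface_elevation = 75,
                          onset_day = 150, turnover_day = 275,
                          epi_temp_peak = 25, peak_day = 210,
                          thermocline_start = 6, thermocline_rate = 0.05,
                          do_depletion = 0.12,
                          n_stations = 21, range_iso_m = 375,
                          range_strat_m = 280, range_jitter = 0.1,
                          n_fish = 8, tag_delay = 120, tag_jitter = 60,
                          time_step = 600, step_scale = 120,
                          step_a = 0.5, step_b = 1.5, step_c = 1,
                          turn_sd = 0.6,
                          emigration_floor = 0.1, emigration_prob = 0.02,
                          fp_rate = 0.2, seed = 42) {
  sc <- as.list(environment())
  if (max_depth <= 0 || surface_area_km2 <= 0 || bowl_exponent <= 0)
    stopf("degenerate basin shape")
  if (onset_day >= turnover_day) stopf("onset must precede turnover")
  if (do_depletion < 0 || thermocline_rate < 0) stopf("rates must be >= 0")
  if (range_strat_m > range_iso_m)
    stopf("stratified ranges must not exceed isothermal ranges")
  class(sc) <- "lake_scenario"
  sc
}

#' Generate a bowl-shaped bathymetry grid
#'
#' Rasterises `depth(x, y) = max_depth * (1 - (rho/rho_max)^p)` at the
#' scenario's cell size; cells beyond `rho_max` are land. The realised
#' surface area is checked to be within 5% of the target.
#'
#' @param scenario a [lake_scenario()].
#' @return A [bathymetry_grid()].
#' @export
gen_bathymetry <- function(scenario) {
  rho_max <- sqrt(scenario$surface_area_km2 * 1e6 / pi)
  cs <- scenario$cell_size
  half <- ceiling(rho_max / cs) + 2L
  n <- 2L * half
  centre <- half * cs  # grid coordinates: lower-left at (0, 0)
  xc <- (seq_len(n) - 0.5) * cs
  rho <- sqrt(outer((xc - centre)^2, (xc - centre)^2, `+`))
  depth <- scenario$max_depth * (1 - (rho / rho_max)^scenario$bowl_exponent)
  depth[rho >= rho_max] <- NA_real_
  bed <- scenario$surface_elevation - depth
  grid <- bathymetry_grid(bed, cell_size = cs,
                          surface_elevation = scenario$surface_elevation)
  realised <- sum(is.finite(depth) & depth > 0) * cs^2
  if (abs(realised / (scenario$surface_area_km2 * 1e6) - 1) > 0.05)
    stopf("realised surface area off target by more than 5%%: refine cell_size")
  attr(grid, "xll") <- 0
  attr(grid, "yll") <- 0
  grid
}

# epilimnion temperature seasonal sinusoid
epi_temp <- function(scenario, doy, peak = scenario$epi_temp_peak) {
  13 + (peak - 13) * cos(2 * pi * (doy - scenario$peak_day) / 365)
}

# near-saturation epilimnetic DO declines with temperature
epi_do <- function(temp_c) pmax(4, 12 - 0.15 * temp_c)

#' Generate daily water-column profiles
#'
#' One profile per day at 1-m depths (0 to `max_depth - 1`). Outside the
#' stratified period the column is isothermal and normoxic. Inside it, a
#' two-layer logistic temperature profile separates a sinusoidally warming
#' epilimnion from a 5 C hypolimnion, the thermocline deepens linearly, and
#' below-thermocline DO declines linearly from its value at onset at the
#' depletion rate, floored at zero. Year-to-year variability (onset, peak
#' temperature, depletion rate) is drawn from seeded streams so a fixed
#' scenario seed reproduces the series exactly.
#'
#' @param scenario a [lake_scenario()].
#' @param years integer vector of calendar years.
#' @param days day-of-year span (default the whole year).
#' @return Data frame `date`, `depth_m`, `temp_c`, `do_mgl`; attribute
#'   `truth` records each year's realised onset/turnover/depletion.
#' @export
gen_profiles <- function(scenario, years, days = 1:365) {
  depths <- 0:(ceiling(scenario$max_depth) - 1L)
  w <- 1.2  # thermocline transition half-width, m
  all <- list(); truth <- list()
  for (yr in years) {
    jit <- with_seed(scenario$seed + 1000L + yr, {
      list(onset = round(stats::rnorm(1, 0, 5)),
           peak = stats::rnorm(1, 0, 1),
           depl = stats::runif(1, 0.85, 1.15))
    })
    onset <- scenario$onset_day + jit$onset
    turnover <- scenario$turnover_day
    depl <- scenario$do_depletion * jit$depl
    peak <- scenario$epi_temp_peak + jit$peak
    do_at_onset <- epi_do(epi_temp(scenario, onset, peak))
    do_prev <- NULL  # hypolimnetic DO ratchet: no re-aeration below the thermocline
    rows <- lapply(days, function(doy) {
      te <- epi_temp(scenario, doy, peak)
      if (doy >= onset && doy < turnover) {
        zt <- scenario$thermocline_start + scenario$thermocline_rate * (doy - onset)
        frac <- stats::plogis((zt - depths) / w)  # 1 in epilimnion, 0 below
        temp <- 5 + (te - 5) * frac
        doh <- max(0, do_at_onset - depl * (doy - onset))
        dox <- doh + (epi_do(te) - doh) * frac
        # no re-aeration at any depth until turnover: DO can only decline
        if (!is.null(do_prev)) dox <- pmin(dox, do_prev)
        do_prev <<- dox
      } else {
        temp <- rep(te, length(depths))
        dox <- rep(epi_do(te), length(depths))
        do_prev <<- NULL
      }
      data.frame(date = as.Date(doy - 1, origin = sprintf("%d-01-01", yr)),
                 depth_m = depths, temp_c = pmin(pmax(temp, 0.5), 35),
                 do_mgl = pmax(dox, 0))
    })
    all[[as.character(yr)]] <- do.call(rbind, rows)
    truth[[as.character(yr)]] <- data.frame(year = yr, onset = onset,
                                            turnover = turnover,
                                            depletion = depl, peak_temp = peak)
  }
  out <- do.call(rbind, all)
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, truth)
  out
}

#' Generate a receiver array
#'
#' Places stations on water deeper than 3 m by greedy farthest-point
#' sampling (well spread, deterministic under the scenario seed) and draws
#' per-station 50%-detection ranges around the scenario means; each
#' station's stratified range uses the same relative perturbation as its
#' isothermal range, preserving the array-wide coverage ratio.
#'
#' @param scenario a [lake_scenario()].
#' @param grid the [gen_bathymetry()] grid.
#' @return Data frame `station_id`, `x`, `y`, `range_iso_m`, `range_strat_m`.
#' @export
gen_stations <- function(scenario, grid) {
  mask <- water_mask(grid, min_depth = 3)
  wet <- which(mask, arr.ind = TRUE)
  xy <- cell_xy(mask, wet[, 1], wet[, 2])
  n <- scenario$n_stations
  with_seed(scenario$seed + 2L, {
    chosen <- integer(n)
    chosen[1] <- sample.int(nrow(xy), 1)
    mind <- sqrt((xy[, 1] - xy[chosen[1], 1])^2 + (xy[, 2] - xy[chosen[1], 2])^2)
    for (i in seq_len(n - 1L) + 1L) {
      chosen[i] <- which.max(mind)
      mind <- pmin(mind, sqrt((xy[, 1] - xy[chosen[i], 1])^2 +
                              (xy[, 2] - xy[chosen[i], 2])^2))
    }
    mult <- stats::runif(n, 1 - scenario$range_jitter, 1 + scenario$range_jitter)
    data.frame(station_id = sprintf("S%02d", seq_len(n)),
               x = xy[chosen, 1], y = xy[chosen, 2],
               range_iso_m = scenario$range_iso_m * mult,
               range_strat_m = scenario$range_strat_m * mult)
  })
}

#' Simulate fish tracks responding to habitat availability
#'
#' Correlated random walk per fish at the scenario time step, constrained to
#' water cells by rejection. The expected step length on each day is
#' `step_scale * (step_a + step_b * optimum_prop) * suitable_prop^step_c`
#' with the day's habitat proportions (here "suitable" is all non-hypoxic
#' water, the suitable and optimum partition classes combined), so movement
#' is suppressed when suitable habitat is compressed and boosted as optimum
#' habitat grows
#' (step lengths are exponential around that mean). When the suitable
#' proportion drops below `emigration_floor`, each fish leaves the array
#' with probability `emigration_prob` per day and its track ends.
#'
#' @param scenario a [lake_scenario()].
#' @param grid the basin grid.
#' @param habitat daily habitat series ([daily_habitat_volumes()]) covering
#'   the simulated dates.
#' @param year calendar year.
#' @param months months to simulate.
#' @return List: `positions` (data frame `transmitter_id`, `time`, `x`, `y`)
#'   and `truth` (data frame `transmitter_id`, `year`, `month`,
#'   `true_path_km`, `emigrated`).
#' @export
gen_tracks <- function(scenario, grid, habitat, year, months = 5:9) {
  mask <- water_mask(grid, min_depth = 1)
  wet <- which(mask, arr.ind = TRUE)
  cs <- attr(mask, "cell_size")
  dates <- seq(as.Date(sprintf("%d-%02d-01", year, min(months))),
               as.Date(sprintf("%d-%02d-01", year, max(months))) +
                 days_in_month(year, max(months)) - 1L, by = "day")
  hidx <- match(dates, as.Date(habitat$date))
  if (anyNA(hidx)) stopf("habitat series does not cover the simulated dates")
  # movement is confined to non-hypoxic water: the behavioural "suitable"
  # proportion is all water with DO above the hypoxia threshold, i.e. the
  # suitable and optimum partition classes combined
  sus <- habitat$prop_suitable[hidx] + habitat$prop_optimum[hidx]
  opt <- habitat$prop_optimum[hidx]
  mean_step <- scenario$step_scale *
    (scenario$step_a + scenario$step_b * opt) * sus^scenario$step_c
  steps_per_day <- as.integer(86400 / scenario$time_step)
  t0 <- as.POSIXct(paste(dates[1], "00:00:00"), tz = "UTC")

  in_water <- function(x, y) {
    rc <- xy_cell(mask, x, y)
    x >= 0 & y >= 0 & x <= ncol(mask) * cs & y <= nrow(mask) * cs &
      mask[rc]
  }
  pos_list <- list(); truth_list <- list()
  for (f in seq_len(scenario$n_fish)) {
    id <- sprintf("F%02d", f)
    with_seed(scenario$seed + 3000L + f, {
      start <- wet[sample.int(nrow(wet), 1), ]
      xy0 <- cell_xy(mask, start[1], start[2])
      x <- xy0[1]; y <- xy0[2]
      heading <- stats::runif(1, 0, 2 * pi)
      n_total <- length(dates) * steps_per_day
      xs <- numeric(n_total); ys <- numeric(n_total); steplen <- numeric(n_total)
      emig_day <- NA_integer_
      k <- 0L
      for (d in seq_along(dates)) {
        if (sus[d] < scenario$emigration_floor &&
            stats::runif(1) < scenario$emigration_prob) {
          emig_day <- d
          break
        }
        for (s in seq_len(steps_per_day)) {
          k <- k + 1L
          len <- stats::rexp(1, 1 / max(mean_step[d], 1e-6))
          moved <- FALSE
          for (try in 1:10) {
            heading_c <- heading + stats::rnorm(1, 0, scenario$turn_sd)
            xn <- x + len * cos(heading_c); yn <- y + len * sin(heading_c)
            if (in_water(xn, yn)) {
              x <- xn; y <- yn; heading <- heading_c; moved <- TRUE
              break
            }
            heading_c <- stats::runif(1, 0, 2 * pi)
            heading <- heading_c
          }
          xs[k] <- x; ys[k] <- y
          steplen[k] <- if (moved) len else 0
        }
      }
      if (k > 0L) {
        tm <- t0 + (seq_len(k) - 1L) * scenario$time_step
        pos_list[[id]] <- data.frame(transmitter_id = id, time = tm,
                                     x = xs[seq_len(k)], y = ys[seq_len(k)])
        mo <- as.integer(format(as.Date(tm, tz = "UTC"), "%m"))
        pl <- tapply(steplen[seq_len(k)], mo, sum) / 1000
        truth_list[[id]] <- data.frame(
          transmitter_id = id, year = year, month = as.integer(names(pl)),
          true_path_km = as.numeric(pl),
          emigrated = !is.na(emig_day))
      }
    })
  }
  list(positions = do.call(rbind, pos_list),
       truth = {
         tr <- do.call(rbind, truth_list); rownames(tr) <- NULL; tr
       })
}

#' Simulate raw acoustic detections from tracks
#'
#' Each fish transmits every `tag_delay` +/- `tag_jitter` seconds (uniform).
#' Every station independently logs a transmission with probability logistic
#' in distance, equal to 0.5 at the station's state-dependent mean range
#' (stratified ranges apply between the scenario's onset and turnover days)
#' and ~1 at distance zero. Spurious singleton detections are injected at
#' rate `fp_rate` per station per day to exercise the false-positive filter;
#' they are listed in the returned attribute `injected_fp`.
#'
#' @param scenario a [lake_scenario()].
#' @param tracks output of [gen_tracks()].
#' @param stations output of [gen_stations()].
#' @return Data frame `detection_timestamp_utc`, `receiver_sn`,
#'   `transmitter_id`, time-sorted; attributes `n_transmissions`,
#'   `injected_fp`.
#' @export
gen_detections <- function(scenario, tracks, stations) {
  pos <- tracks$positions
  if (is.null(pos) || nrow(pos) == 0L) stopf("no track positions")
  det_list <- list()
  n_tx_total <- 0L
  slope <- 6  # logistic steepness: p(0) = plogis(6) ~ 0.998
  for (id in unique(pos$transmitter_id)) {
    p <- pos[pos$transmitter_id == id, ]
    t0 <- as.numeric(p$time[1]); t1 <- as.numeric(p$time[nrow(p)])
    tx <- with_seed(scenario$seed + 4000L + as.integer(sub("\\D+", "", id)), {
      n_max <- ceiling((t1 - t0) / (scenario$tag_delay - scenario$tag_jitter)) + 2L
      gaps <- scenario$tag_delay +
        stats::runif(n_max, -scenario$tag_jitter, scenario$tag_jitter)
      tt <- t0 + cumsum(gaps)
      tt <- tt[tt <= t1]
      xi <- stats::approx(as.numeric(p$time), p$x, xout = tt)$y
      yi <- stats::approx(as.numeric(p$time), p$y, xout = tt)$y
      doy <- as.integer(format(as.Date(as.POSIXct(tt, tz = "UTC",
                                                  origin = "1970-01-01")), "%j"))
      strat <- doy >= scenario$onset_day & doy < scenario$turnover_day
      hits <- list()
      for (s in seq_len(nrow(stations))) {
        d <- sqrt((xi - stations$x[s])^2 + (yi - stations$y[s])^2)
        r50 <- ifelse(strat, stations$range_strat_m[s], stations$range_iso_m[s])
        pr <- stats::plogis(slope * (1 - d / r50))
        cand <- which(pr > 1e-6)
        got <- cand[stats::runif(length(cand)) < pr[cand]]
        if (length(got))
          hits[[s]] <- data.frame(detection_timestamp_utc = tt[got],
                                  receiver_sn = stations$station_id[s],
                                  transmitter_id = id)
      }
      list(hits = do.call(rbind, hits), n_tx = length(tt))
    })
    n_tx_total <- n_tx_total + tx$n_tx
    det_list[[id]] <- tx$hits
  }
  det <- do.call(rbind, det_list)
  # spurious singletons: random station/time/transmitter
  span <- range(as.numeric(pos$time))
  n_days <- (span[2] - span[1]) / 86400
  fp <- with_seed(scenario$seed + 5L, {
    n_fp <- stats::rpois(1, scenario$fp_rate * nrow(stations) * n_days)
    if (n_fp == 0L) NULL else
      data.frame(detection_timestamp_utc = stats::runif(n_fp, span[1], span[2]),
                 receiver_sn = sample(stations$station_id, n_fp, replace = TRUE),
                 transmitter_id = sample(unique(pos$transmitter_id), n_fp,
                                         replace = TRUE))
  })
  det <- rbind(det, fp)
  if (is.null(det))
    det <- data.frame(detection_timestamp_utc = numeric(),
                      receiver_sn = character(), transmitter_id = character())
  det$detection_timestamp_utc <- as.POSIXct(det$detection_timestamp_utc,
                                            tz = "UTC", origin = "1970-01-01")
  det <- det[order(det$detection_timestamp_utc), ]
  rownames(det) <- NULL
  attr(det, "n_transmissions") <- n_tx_total
  attr(det, "injected_fp") <- fp
  det
}

#' Run the full synthetic study
#'
#' Generates basin, profiles, habitat series, receiver array, fish tracks
#' and raw detections for one year under a single scenario seed, returning
#' every intermediate object plus ground truth.
#'
#' @param scenario a [lake_scenario()].
#' @param year calendar year (default 2017).
#' @param months simulated months (default May-September).
#' @return List with `scenario`, `grid`, `curve`, `profiles`, `daily`,
#'   `habitat`, `stations`, `tracks`, `detections`, `states`.
#' @export
simulate_study <- function(scenario = lake_scenario(), year = 2017,
                           months = 5:9) {
  grid <- gen_bathymetry(scenario)
  curve <- compute_hypsographic_curve(grid)
  profiles <- gen_profiles(scenario, year)
  daily <- aggregate_daily_profiles(profiles, n_strata = nrow(curve))
  habitat <- daily_habitat_volumes(daily, curve)
  stations <- gen_stations(scenario, grid)
  tracks <- gen_tracks(scenario, grid, habitat, year, months)
  detections <- gen_detections(scenario, tracks, stations)
  states <- classify_stratification_state(daily)
  list(scenario = scenario, grid = grid, curve = curve, profiles = profiles,
       daily = daily, habitat = habitat, stations = stations, tracks = tracks,
       detections = detections, states = states)
}
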