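#' Oxythermal habitat thresholds
#'
#' Dissolved-oxygen and temperature thresholds that partition the water
#' column into three mutually exclusive categories: *hypoxic* (DO below
#' `hypoxia_do`), *optimum* (DO above `optimum_do` and temperature inside
#' `optimum_temp`), and *suitable* (everything else, i.e. non-hypoxic water
#' outside the optimum window). Defaults follow field observations for
#' cool-water percids: hypoxia below 3 mg/L, optimum above 5 mg/L at
#' 18-23 degrees C.
#'
#' @param hypoxia_do hypoxia threshold, mg/L (strict: DO < threshold is
#'   hypoxic).
#' @param optimum_do optimum DO threshold, mg/L (strict: DO > threshold
#'   required).
#' @param optimum_temp length-2 numeric, inclusive temperature band in
#'   degrees C.
#' @return An object of class `habitat_thresholds`.
#' @export
habitat_thresholds <- function(hypoxia_do = 3, optimum_do = 5,
                               optimum_temp = c(18, 23)) {
  if (!is.numeric(hypoxia_do) || !is.numeric(optimum_do) ||
      hypoxia_do >= optimum_do)
    stopf("invalid thresholds: hypoxia_do must be below optimum_do")
  if (length(optimum_temp) != 2L || optimum_temp[1] >= optimum_temp[2])
    stopf("optimum_temp must be an increasing length-2 range")
  structure(list(hypoxia_do = hypoxia_do, optimum_do = optimum_do,
                 optimum_temp = as.numeric(optimum_temp)),
            class = "habitat_thresholds")
}

#' Classify water by temperature and dissolved oxygen
#'
#' Vectorised classification of water parcels. Hypoxia takes precedence;
#' optimum is carved out of the non-hypoxic water; all remaining non-hypoxic
#' water is suitable. DO thresholds are strict inequalities ("above 3 mg/L",
#' "above 5 mg/L"), the temperature band is inclusive, so DO exactly at a
#' threshold falls to suitable.
#'
#' @param temp_c temperature, degrees C.
#' @param do_mgl dissolved oxygen, mg/L.
#' @param thresholds a [habitat_thresholds()].
#' @return Character vector in `c("hypoxic", "suitable", "optimum")`.
#' @examples
#' classify_habitat(c(20, 20, 25), c(6, 2, 8))
#' @export
classify_habitat <- function(temp_c, do_mgl, thresholds = habitat_thresholds()) {
  if (length(temp_c) != length(do_mgl))
    stopf("temp_c and do_mgl must have equal length")
  if (any(!is.finite(temp_c)) || any(!is.finite(do_mgl)))
    stopf("non-finite temperature or DO value")
  if (any(do_mgl < 0)) stopf("negative dissolved oxygen")
  out <- rep("suitable", length(temp_c))
  out[do_mgl < thresholds$hypoxia_do] <- "hypoxic"
  opt <- do_mgl > thresholds$optimum_do &
    temp_c >= thresholds$optimum_temp[1] & temp_c <= thresholds$optimum_temp[2] &
    out != "hypoxic"
  out[opt] <- "optimum"
  out
}

#' Aggregate sub-daily profile casts to one profile per day and 1-m stratum
#'
#' Profiler buoys record several casts per day at roughly 1-m spacing. This
#' collapses them to a single daily profile on the nominal strata `1..n`:
#' readings are binned to the nearest integer metre (surface readings to
#' stratum 1), averaged within a day-stratum, then missing strata are filled
#' by linear interpolation between measured depths with constant
#' extrapolation at the ends. Filled strata are flagged.
#'
#' @param profiles data frame with columns `date` (Date or ISO-8601
#'   character), `depth_m`, `temp_c`, `do_mgl`.
#' @param n_strata number of 1-m strata to cover (typically
#'   `nrow(hypsographic curve)`).
#' @return Data frame with one row per day and stratum: `date`, `stratum`,
#'   `temp_c`, `do_mgl`, `filled` (logical).
#' @export
aggregate_daily_profiles <- function(profiles, n_strata) {
  assert_cols(profiles, c("date", "depth_m", "temp_c", "do_mgl"), "profiles")
  if (!is_count(n_strata)) stopf("n_strata must be a positive integer")
  profiles$date <- as.Date(profiles$date)
  ok <- is.finite(profiles$depth_m) & is.finite(profiles$temp_c) &
    is.finite(profiles$do_mgl)
  if (!all(ok)) {
    warnf("dropping %d profile row(s) with missing values", sum(!ok))
    profiles <- profiles[ok, ]
  }
  if (nrow(profiles) == 0L) stopf("no usable profile rows")
  if (any(profiles$temp_c <= -1 | profiles$temp_c >= 40))
    stopf("temperature outside physical bounds (-1, 40) C")
  if (any(profiles$do_mgl < 0)) stopf("negative dissolved oxygen")
  profiles$stratum <- pmax(1L, as.integer(round_half_up(profiles$depth_m)))

  per_day <- split(profiles, profiles$date)
  out <- lapply(per_day, function(d) {
    mt <- tapply(d$temp_c, d$stratum, mean)
    mo <- tapply(d$do_mgl, d$stratum, mean)
    meas <- as.integer(names(mt))
    strata <- seq_len(n_strata)
    # rule = 2: constant extrapolation beyond the measured range
    tt <- if (length(meas) == 1L) rep(mt[[1]], n_strata)
          else stats::approx(meas, as.numeric(mt), xout = strata, rule = 2)$y
    oo <- if (length(meas) == 1L) rep(mo[[1]], n_strata)
          else stats::approx(meas, as.numeric(mo), xout = strata, rule = 2)$y
    data.frame(date = d$date[1L], stratum = strata, temp_c = tt, do_mgl = oo,
               filled = !(strata %in% meas))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Daily habitat volumes from classified strata
#'
#' Assigns each 1-m stratum its volume from the hypsographic curve and
#' accrues it to the stratum's habitat category. Because the three categories
#' partition the water column, the three volumes sum exactly to total lake
#' volume every day.
#'
#' @param daily output of [aggregate_daily_profiles()] (columns `date`,
#'   `stratum`, `temp_c`, `do_mgl`).
#' @param curve a `hypsographic_curve`; the profile must cover (possibly by
#'   fill) every stratum of the curve.
#' @param thresholds a [habitat_thresholds()].
#' @return Data frame of class `habitat_volume_series`: one row per day with
#'   `date`, `volume_hypoxic`, `volume_suitable`, `volume_optimum` (m^3) and
#'   `prop_hypoxic`, `prop_suitable`, `prop_optimum`; attribute
#'   `total_volume`.
#' @export
daily_habitat_volumes <- function(daily, curve,
                                  thresholds = habitat_thresholds()) {
  assert_cols(daily, c("date", "stratum", "temp_c", "do_mgl"), "daily profiles")
  if (!inherits(curve, "hypsographic_curve")) stopf("curve must be a hypsographic_curve")
  n <- nrow(curve)
  tot <- total_volume(curve)
  daily$date <- as.Date(daily$date)
  per_day <- split(daily, daily$date)
  rows <- lapply(per_day, function(d) {
    d <- d[order(d$stratum), ]
    if (!identical(d$stratum, curve$stratum))
      stopf("day %s does not cover every stratum of the curve exactly once",
            format(d$date[1L]))
    lab <- classify_habitat(d$temp_c, d$do_mgl, thresholds)
    v <- vapply(c("hypoxic", "suitable", "optimum"),
                function(k) sum(curve$volume_m3[lab == k]), numeric(1))
    data.frame(date = d$date[1L],
               volume_hypoxic = v[["hypoxic"]],
               volume_suitable = v[["suitable"]],
               volume_optimum = v[["optimum"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$prop_hypoxic <- out$volume_hypoxic / tot
  out$prop_suitable <- out$volume_suitable / tot
  out$prop_optimum <- out$volume_optimum / tot
  structure(out, class = c("habitat_volume_series", "data.frame"),
            total_volume = tot)
}

#' Monthly mean habitat volumes
#'
#' Arithmetic mean of the daily category volumes over the days available in
#' each month. Months with fewer than `min_days` profiled days are kept but
#' flagged as low coverage.
#'
#' @param series a `habitat_volume_series`.
#' @param min_days minimum days for full-coverage status (default 3).
#' @return Data frame with `year`, `month`, `n_days`, `low_coverage`, and the
#'   mean `volume_*` / `prop_*` columns.
#' @export
monthly_mean_volumes <- function(series, min_days = 3L) {
  assert_cols(series, c("date", "volume_hypoxic", "volume_suitable",
                        "volume_optimum"), "habitat series")
  yr <- as.integer(format(series$date, "%Y"))
  mo <- as.integer(format(series$date, "%m"))
  key <- paste(yr, mo, sep = "-")
  cols <- grep("^(volume|prop)_", names(series), value = TRUE)
  agg <- lapply(split(seq_len(nrow(series)), key), function(idx) {
    cbind(data.frame(year = yr[idx[1]], month = mo[idx[1]],
                     n_days = length(idx)),
          as.data.frame(lapply(series[idx, cols, drop = FALSE], mean)))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$year, out$month), ]
  rownames(out) <- NULL
  out$low_coverage <- out$n_days < min_days
  if (any(out$low_coverage))
    warnf("%d month(s) have fewer than %d profiled days",
          sum(out$low_coverage), min_days)
  out
}

#' Seasonal comparison window
#'
#' The fixed 27 May - 2 October window (129 days in a non-leap year, by
#' inclusive calendar difference) over which years are compared; both
#' endpoints fall after February so leap day does not change the count.
#'
#' @param start,end month-day strings `"MM-DD"`.
#' @return List with `start`, `end`, `n_days`.
#' @export
season_window <- function(start = "05-27", end = "10-02") {
  n <- as.integer(as.Date(paste0("2017-", end)) -
                  as.Date(paste0("2017-", start))) + 1L
  if (n <= 0L) stopf("season window end precedes start")
  list(start = start, end = end, n_days = n)
}

#' Seasonal cumulative habitat proportions
#'
#' For each year, restricts the daily series to the seasonal window, sums the
#' daily category volumes, and divides by the cumulative available volume
#' `n_days * total_volume` to give one cumulative proportion per category per
#' year; also reports the min/max/mean of the daily proportions. With
#' `strict = TRUE` the denominator uses the observed day count instead of the
#' nominal window length, rescaling for missing days (logged).
#'
#' @param series a `habitat_volume_series`.
#' @param total_volume lake volume, m^3 (defaults to the series attribute).
#' @param window a [season_window()].
#' @param strict rescale the denominator by observed days (default `FALSE`:
#'   missing days reduce the numerator only, as when comparing against a
#'   fixed 129-day season).
#' @return Data frame, one row per year and category: `year`, `category`,
#'   `n_days_observed`, `cumulative_proportion`, `daily_min`, `daily_max`,
#'   `daily_mean` (daily values as proportions of total volume).
#' @export
seasonal_summary <- function(series, total_volume = attr(series, "total_volume"),
                             window = season_window(), strict = FALSE) {
  assert_cols(series, c("date", "volume_hypoxic", "volume_suitable",
                        "volume_optimum"), "habitat series")
  if (is.null(total_volume)) stopf("total_volume is required")
  yr <- as.integer(format(series$date, "%Y"))
  md <- format(series$date, "%m-%d")
  keep <- md >= window$start & md <= window$end
  series <- series[keep, ]; yr <- yr[keep]
  if (nrow(series) == 0L) stopf("no days inside the seasonal window")
  cats <- c("hypoxic", "suitable", "optimum")
  out <- lapply(split(seq_len(nrow(series)), yr), function(idx) {
    nobs <- length(idx)
    denom_days <- if (strict) nobs else window$n_days
    if (strict && nobs < window$n_days)
      message(sprintf("year %d: rescaling by %d observed days (window is %d)",
                      yr[idx[1]], nobs, window$n_days))
    do.call(rbind, lapply(cats, function(k) {
      v <- series[[paste0("volume_", k)]][idx]
      p <- v / total_volume
      data.frame(year = yr[idx[1]], category = k, n_days_observed = nobs,
                 cumulative_proportion = sum(v) / (denom_days * total_volume),
                 daily_min = min(p), daily_max = max(p), daily_mean = mean(p))
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
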