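#' Read an acoustic detection log
#'
#' Reads a GLATOS-style detection CSV (`detection_timestamp_utc`,
#' `receiver_sn`, `transmitter_id`, extra columns passed through), parses
#' timestamps as UTC, drops and counts malformed rows, and returns the log
#' time-sorted.
#'
#' @param path CSV path.
#' @return Detections data frame; attribute `n_malformed` counts dropped
#'   rows. An empty (header-only) file returns an empty log with a warning.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_cols(df, c("detection_timestamp_utc", "receiver_sn", "transmitter_id"),
              sprintf("detection file %s", basename(path)))
  if (nrow(df) == 0L) {
    warnf("empty detection file: %s", basename(path))
    df$detection_timestamp_utc <- as.POSIXct(character(), tz = "UTC")
    attr(df, "n_malformed") <- 0L
    return(df)
  }
  ts <- as.POSIXct(strptime(df$detection_timestamp_utc,
                            "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
  alt <- is.na(ts)
  ts[alt] <- as.POSIXct(strptime(df$detection_timestamp_utc[alt],
                                 "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
  bad <- is.na(ts) | is.na(df$receiver_sn) | is.na(df$transmitter_id)
  if (any(bad)) warnf("dropping %d malformed detection row(s)", sum(bad))
  df <- df[!bad, , drop = FALSE]
  df$detection_timestamp_utc <- ts[!bad]
  df <- df[order(df$detection_timestamp_utc), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_malformed") <- sum(bad)
  df
}

#' Read a receiver station table
#'
#' @param path CSV with `station_id`, `x`, `y` and optionally `range_iso_m`,
#'   `range_strat_m`, deployment dates.
#' @return Station data frame.
#' @export
read_stations <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_cols(df, c("station_id", "x", "y"), "station file")
  df
}

#' Read a water-column profile time series
#'
#' @param path CSV with `date` (ISO-8601), `depth_m`, `temp_c`, `do_mgl`.
#' @return Profile data frame with `date` parsed as `Date`.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_cols(df, c("date", "depth_m", "temp_c", "do_mgl"), "profile file")
  df$date <- as.Date(df$date)
  df
}

#' Read an age-length table
#'
#' @param path CSV with `age_years`, `fork_length_mm` (optional `site`).
#' @return Data frame.
#' @export
read_age_length <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_cols(df, c("age_years", "fork_length_mm"), "age-length file")
  df
}

#' Pipeline configuration
#'
#' Bundles thresholds, QC settings and options for [run_pipeline()]. With no
#' input paths the pipeline runs on the synthetic scenario.
#'
#' @param scenario a [lake_scenario()] used when no real inputs are given.
#' @param thresholds a [habitat_thresholds()].
#' @param qc a [qc_config()] (its `min_ping_interval` defaults to the
#'   scenario's minimum transmission interval).
#' @param months months analysed (default April-November).
#' @param year study year for the synthetic run.
#' @param sim_months months simulated by the track generator.
#' @param residency_threshold minimum monthly residency.
#' @param n_perm,alpha permutation-test settings.
#' @param qc_enabled set `FALSE` to let the network stage consume raw
#'   detections (flagged in the manifest).
#' @param seed master seed (overrides the scenario's).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = lake_scenario(),
                            thresholds = habitat_thresholds(),
                            qc = NULL, months = 4:11, year = 2017,
                            sim_months = 5:9,
                            residency_threshold = 0.75,
                            n_perm = 200, alpha = 0.05,
                            qc_enabled = TRUE, seed = NULL) {
  if (!is.null(seed)) scenario$seed <- seed
  if (is.null(qc))
    qc <- qc_config(nominal_delay = scenario$tag_delay,
                    min_ping_interval = scenario$tag_delay - scenario$tag_jitter)
  structure(list(scenario = scenario, thresholds = thresholds, qc = qc,
                 months = months, year = year, sim_months = sim_months,
                 residency_threshold = residency_threshold, n_perm = n_perm,
                 alpha = alpha, qc_enabled = qc_enabled),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> hypsometry -> habitat -> QC -> spatial -> networks ->
#' displacement -> habitat model on the configured synthetic scenario and
#' returns every stage output plus a manifest of row counts, seeds and
#' decisions (auditable provenance for each stage).
#'
#' @param config a [pipeline_config()].
#' @param fit_model fit the displacement GAMM when enough rows survive
#'   (default `TRUE`).
#' @return List of class `oxytel_pipeline` with stage outputs (`sim`,
#'   `curve`, `habitat`, `monthly`, `detections_qc`, `pairs`, `states`,
#'   `movement`, `frame`, `selection`) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), fit_model = TRUE) {
  if (!inherits(config, "pipeline_config")) stopf("config must be a pipeline_config")
  manifest <- list(seed = config$scenario$seed,
                   adjustment_factor = "ratio of summed 50% radii (reconstruction)",
                   null_model = "visit-sequence shuffle, distinct-edge statistic",
                   qc_enabled = config$qc_enabled,
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  sim <- simulate_study(config$scenario, year = config$year,
                        months = config$sim_months)
  note("simulate", n_detections = nrow(sim$detections),
       n_fish = length(unique(sim$tracks$positions$transmitter_id)))

  curve <- sim$curve
  note("hypsometry", n_strata = nrow(curve), total_volume = total_volume(curve))

  habitat <- sim$habitat
  monthly <- monthly_mean_volumes(habitat)
  note("habitat", n_days = nrow(habitat), n_months = nrow(monthly))

  det <- sim$detections
  if (config$qc_enabled) {
    det <- filter_false_positives(det, config$qc)
    n_fp <- attr(det, "n_removed")
    det <- dedupe_min_interval(det, config$qc)
    note("qc", input = nrow(sim$detections), removed_false_positive = n_fp,
         removed_dedupe = attr(det, "n_removed"), retained = nrow(det))
  } else {
    note("qc", skipped = TRUE, warning = "network stage consumes raw detections")
  }

  mask <- water_mask(sim$grid, min_depth = 1)
  pairs <- station_pairs(mask, sim$stations)
  states <- sim$states
  note("spatial", n_pairs = nrow(pairs),
       n_stratified_months = sum(states$state == "stratified"))

  roster <- data.frame(transmitter_id =
                         unique(sim$tracks$positions$transmitter_id))
  res <- residency(det, roster)
  eligible <- residency_filter(res$fish, config$residency_threshold)
  note("residency", n_fish_months = nrow(res$fish), n_eligible = nrow(eligible))

  mv <- movement_analysis(det, eligible, pairs, states,
                          months = config$months, n_perm = config$n_perm,
                          alpha = config$alpha, seed = config$scenario$seed)
  note("networks", n_networks = length(mv$networks),
       n_significant = sum(mv$significance$significant))
  note("displacement", n_records = nrow(mv$displacement))

  frame <- if (nrow(mv$displacement))
    model_frame(mv$displacement, monthly) else NULL
  selection <- NULL
  if (fit_model && !is.null(frame) && sum(frame$displacement_km > 0) >= 20) {
    selection <- backward_select(frame, candidates = c("suitable", "optimum"),
                                 stage = "full_period")
    note("model", best = selection$best, n = selection$n)
  } else note("model", skipped = TRUE)

  structure(list(sim = sim, curve = curve, habitat = habitat,
                 monthly = monthly, detections_qc = det, pairs = pairs,
                 states = states, residency = res, eligible = eligible,
                 movement = mv, frame = frame, selection = selection,
                 manifest = manifest),
            class = "oxytel_pipeline")
}

#' @export
print.oxytel_pipeline <- function(x, ...) {
  cat("oxytel pipeline run\n")
  for (s in names(x$manifest$stages)) {
    info <- x$manifest$stages[[s]]
    cat(sprintf("  %-12s %s\n", s,
                paste(names(info), unlist(lapply(info, format)), sep = "=",
                      collapse = ", ")))
  }
  invisible(x)
}
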