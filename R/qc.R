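#' Detection QC configuration
#'
#' @param nominal_delay nominal tag transmission delay, seconds (default 120).
#' @param fp_multiplier false-positive gap multiplier (default 30): a
#'   detection is spurious when its nearest same-transmitter same-receiver
#'   neighbour is more than `fp_multiplier * nominal_delay` seconds away.
#' @param min_ping_interval minimum transmitter pinging interval across the
#'   tag set, seconds (must be supplied before [dedupe_min_interval()]).
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(nominal_delay = 120, fp_multiplier = 30,
                      min_ping_interval = NULL) {
  if (nominal_delay <= 0 || fp_multiplier <= 0)
    stopf("nominal_delay and fp_multiplier must be positive")
  if (!is.null(min_ping_interval) && min_ping_interval <= 0)
    stopf("min_ping_interval must be positive")
  structure(list(nominal_delay = nominal_delay, fp_multiplier = fp_multiplier,
                 min_ping_interval = min_ping_interval),
            class = "qc_config")
}

check_detections <- function(detections) {
  assert_cols(detections,
              c("detection_timestamp_utc", "transmitter_id", "receiver_sn"),
              "detections")
  if (!inherits(detections$detection_timestamp_utc, "POSIXct"))
    detections$detection_timestamp_utc <-
      as.POSIXct(detections$detection_timestamp_utc, tz = "UTC")
  detections
}

#' Remove false-positive detections by the min-gap rule
#'
#' Within each (transmitter, receiver) series sorted by time, a detection is
#' removed iff the smaller of its gaps to the previous and next detection of
#' the same series exceeds `fp_multiplier * nominal_delay` seconds (3600 s at
#' defaults, i.e. 30 times a 120-s delay; strict ">", so a pair exactly at
#' the threshold is retained). A series of size one has both gaps infinite
#' and is removed: a lone ping with no temporal neighbour is the canonical
#' false positive.
#'
#' @param detections data frame with `detection_timestamp_utc` (POSIXct or
#'   parseable), `transmitter_id`, `receiver_sn`.
#' @param cfg a [qc_config()].
#' @return The retained detections, time-sorted, with attribute
#'   `removal_report` (data frame of removed counts per receiver) and
#'   `n_removed`.
#' @export
filter_false_positives <- function(detections, cfg = qc_config()) {
  detections <- check_detections(detections)
  threshold <- cfg$fp_multiplier * cfg$nominal_delay
  t <- as.numeric(detections$detection_timestamp_utc)
  key <- paste(detections$transmitter_id, detections$receiver_sn, sep = "\r")
  keep <- logical(nrow(detections))
  for (idx in split(seq_len(nrow(detections)), key)) {
    idx <- idx[order(t[idx])]
    n <- length(idx)
    if (n == 1L) next  # singleton: removed
    gaps <- diff(t[idx])
    gap_prev <- c(Inf, gaps)
    gap_next <- c(gaps, Inf)
    keep[idx] <- pmin(gap_prev, gap_next) <= threshold
  }
  removed <- detections[!keep, , drop = FALSE]
  report <- if (nrow(removed)) {
    as.data.frame(table(receiver_sn = removed$receiver_sn),
                  responseName = "n_removed")
  } else data.frame(receiver_sn = character(), n_removed = integer())
  out <- detections[keep, , drop = FALSE]
  out <- out[order(out$detection_timestamp_utc), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removal_report") <- report
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Remove detections closer than the minimum pinging interval
#'
#' Receivers with overlapping acoustic ranges can log the same transmission
#' more than once, inflating apparent presence. Scanning each transmitter's
#' detections chronologically across all receivers, any detection strictly
#' closer than `min_ping_interval` seconds to the previously *retained*
#' detection of that transmitter is dropped (keep-first greedy; a detection
#' exactly at the interval is kept).
#'
#' @inheritParams filter_false_positives
#' @return Retained detections with attribute `n_removed`.
#' @export
dedupe_min_interval <- function(detections, cfg) {
  if (is.null(cfg$min_ping_interval))
    stopf(paste("min_ping_interval is not set: derive it from the tag",
                "specification table (the smallest nominal delay minus jitter",
                "across all deployed transmitters) and set it in qc_config()"))
  detections <- check_detections(detections)
  t <- as.numeric(detections$detection_timestamp_utc)
  keep <- logical(nrow(detections))
  for (idx in split(seq_len(nrow(detections)), detections$transmitter_id)) {
    idx <- idx[order(t[idx])]
    last_kept <- -Inf
    for (i in idx) {
      if (t[i] - last_kept >= cfg$min_ping_interval) {
        keep[i] <- TRUE
        last_kept <- t[i]
      }
    }
  }
  out <- detections[keep, , drop = FALSE]
  out <- out[order(out$detection_timestamp_utc), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Monthly residency from detections
#'
#' Fish-level residency is the fraction of days in the month with at least
#' one detection; array-level residency is the percentage of the active
#' roster detected at least once that month.
#'
#' @param detections QC-filtered detections.
#' @param roster data frame of tagged fish with `transmitter_id` and
#'   (optionally) `active_from`, `active_to` dates bounding when each fish
#'   was at liberty; fish are counted in a month's roster when the month
#'   overlaps that interval.
#' @return List with `fish` (per transmitter-year-month: `n_days_detected`,
#'   `residency` in [0, 1]) and `array` (per year-month: `n_active`,
#'   `n_detected`, `pct_detected`).
#' @export
residency <- function(detections, roster) {
  detections <- check_detections(detections)
  assert_cols(roster, "transmitter_id", "tag roster")
  if (is.null(roster$active_from)) roster$active_from <- as.Date("1900-01-01")
  if (is.null(roster$active_to)) roster$active_to <- as.Date("2999-12-31")
  roster$active_from <- as.Date(roster$active_from)
  roster$active_to <- as.Date(roster$active_to)

  day <- as.Date(detections$detection_timestamp_utc, tz = "UTC")
  yr <- as.integer(format(day, "%Y"))
  mo <- as.integer(format(day, "%m"))
  key <- paste(detections$transmitter_id, yr, mo, sep = "\r")
  fish <- do.call(rbind, lapply(split(day, key), function(d) {
    data.frame(n_days_detected = length(unique(d)))
  }))
  parts <- do.call(rbind, strsplit(rownames(fish), "\r"))
  fish <- data.frame(transmitter_id = parts[, 1],
                     year = as.integer(parts[, 2]),
                     month = as.integer(parts[, 3]),
                     n_days_detected = fish$n_days_detected)
  fish$residency <- fish$n_days_detected /
    mapply(days_in_month, fish$year, fish$month)
  fish <- fish[order(fish$transmitter_id, fish$year, fish$month), ]
  rownames(fish) <- NULL

  months <- unique(fish[, c("year", "month")])
  arr <- do.call(rbind, lapply(seq_len(nrow(months)), function(i) {
    y <- months$year[i]; m <- months$month[i]
    m_start <- as.Date(sprintf("%d-%02d-01", y, m))
    m_end <- m_start + days_in_month(y, m) - 1L
    active <- roster$transmitter_id[roster$active_from <= m_end &
                                    roster$active_to >= m_start]
    if (length(active) == 0L) return(NULL)  # empty roster month: undefined
    det <- fish$transmitter_id[fish$year == y & fish$month == m]
    data.frame(year = y, month = m, n_active = length(active),
               n_detected = sum(active %in% det),
               pct_detected = 100 * sum(active %in% det) / length(active))
  }))
  arr <- arr[order(arr$year, arr$month), ]
  rownames(arr) <- NULL
  list(fish = fish, array = arr)
}

#' Apply the minimum monthly residency filter
#'
#' @param residency_fish the `fish` table from [residency()].
#' @param threshold minimum residency (default 0.75, inclusive).
#' @return The eligible fish-month rows.
#' @export
residency_filter <- function(residency_fish, threshold = 0.75) {
  assert_cols(residency_fish, c("transmitter_id", "year", "month", "residency"),
              "residency table")
  out <- residency_fish[residency_fish$residency >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
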