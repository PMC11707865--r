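#' Water mask from a bathymetry grid
#'
#' @param grid a [bathymetry_grid()].
#' @param min_depth minimum depth (m) for a cell to count as navigable water.
#' @return Logical matrix of class `water_mask` (TRUE = water) with
#'   attributes `cell_size`, `xll`, `yll` (grid origin; row 1 is the
#'   northernmost row).
#' @export
water_mask <- function(grid, min_depth = 0) {
  depth <- grid_depth(grid)
  m <- is.finite(depth) & depth > min_depth
  structure(m, class = c("water_mask", class(m)),
            cell_size = grid$cell_size,
            xll = attr(grid, "xll") %||% 0,
            yll = attr(grid, "yll") %||% 0)
}

# cell centre coordinates for a (row, col) pair
cell_xy <- function(mask, row, col) {
  cs <- attr(mask, "cell_size")
  cbind(x = attr(mask, "xll") + (col - 0.5) * cs,
        y = attr(mask, "yll") + (nrow(mask) - row + 0.5) * cs)
}

# nearest (row, col) for x/y coordinates
xy_cell <- function(mask, x, y) {
  cs <- attr(mask, "cell_size")
  col <- pmin(pmax(ceiling((x - attr(mask, "xll")) / cs), 1L), ncol(mask))
  row <- pmin(pmax(nrow(mask) - ceiling((y - attr(mask, "yll")) / cs) + 1L, 1L),
              nrow(mask))
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Snap stations to water cells
#'
#' Each station is assigned its grid cell; stations on land are moved to the
#' nearest water cell if one exists within `tolerance` cells, otherwise this
#' is treated as a data error.
#'
#' @param mask a [water_mask()].
#' @param stations data frame with `station_id`, `x`, `y` (same projected
#'   coordinate system as the grid, metres).
#' @param tolerance snap radius in cells (default 3).
#' @return `stations` with integer columns `row`, `col` appended.
#' @export
snap_stations <- function(mask, stations, tolerance = 3) {
  assert_cols(stations, c("station_id", "x", "y"), "stations")
  rc <- xy_cell(mask, stations$x, stations$y)
  wet <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(rc))) {
    if (mask[rc[i, 1], rc[i, 2]]) next
    d2 <- (wet[, 1] - rc[i, 1])^2 + (wet[, 2] - rc[i, 2])^2
    j <- which.min(d2)
    if (length(j) == 0L || sqrt(d2[j]) > tolerance)
      stopf("station %s is on land beyond the %g-cell snap tolerance",
            stations$station_id[i], tolerance)
    rc[i, ] <- wet[j, ]
  }
  stations$row <- rc[, 1]
  stations$col <- rc[, 2]
  stations
}

# igraph over the 8-connected water-cell lattice; vertex names are cell
# indices into `mask`, edge weights in metres
water_graph <- function(mask) {
  cs <- attr(mask, "cell_size")
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  edges <- list(); w <- list(); e <- 0L
  # right, down, down-right, up-right: each undirected pair once
  for (off in list(c(0L, 1L, cs), c(1L, 0L, cs),
                   c(1L, 1L, cs * sqrt(2)), c(-1L, 1L, cs * sqrt(2)))) {
    r2 <- row + off[1]; c2 <- col + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- mask[j]
    e <- e + 1L
    edges[[e]] <- rbind(idx[ok][ok2], j[ok2])
    w[[e]] <- rep(off[3], sum(ok2))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  igraph::V(g)$name <- as.character(idx)
  el <- do.call(cbind, edges)
  g <- igraph::add_edges(g, as.character(as.vector(el)),
                         weight = unlist(w))
  g
}

#' In-water least-cost distances between stations
#'
#' Shortest 8-connected paths through water cells (orthogonal step =
#' `cell_size`, diagonal = `cell_size * sqrt(2)`), Dijkstra on the lattice
#' graph. Distances are symmetric and zero on the diagonal.
#'
#' @param mask a [water_mask()].
#' @param stations station table (see [snap_stations()]).
#' @param tolerance snap radius in cells.
#' @return Symmetric matrix of distances in metres, dimnames = station ids.
#'   Stations in disconnected water bodies raise an error.
#' @export
least_cost_distances <- function(mask, stations, tolerance = 3) {
  st <- snap_stations(mask, stations, tolerance)
  g <- water_graph(mask)
  cellid <- as.character((st$col - 1L) * nrow(mask) + st$row)
  d <- igraph::distances(g, v = cellid, to = cellid,
                         weights = igraph::E(g)$weight, algorithm = "dijkstra")
  if (any(!is.finite(d)))
    stopf("some stations lie in disconnected water bodies (no in-water path)")
  dimnames(d) <- list(st$station_id, st$station_id)
  d
}

#' Detection-range adjustment factor for a receiver pair
#'
#' Under stratification the 50%-detection radius of a receiver shrinks, so a
#' movement observed then is under-counted relative to isothermal months.
#' The implemented factor is the ratio of summed isothermal radii to summed
#' state radii, `(r_iso(a) + r_iso(b)) / (r_state(a) + r_state(b))`: it is 1
#' under isothermal conditions and up-weights movements recorded when
#' coverage is reduced, restoring cross-season comparability. The published
#' construction sits in unavailable supplementary material, so this form is
#' a reconstruction; supply `factor_fun` to substitute another.
#'
#' @param ranges data frame with `station_id`, `range_iso_m`,
#'   `range_strat_m` (50%-detection radii, metres).
#' @param a,b station ids.
#' @param state `"isothermal"` or `"stratified"`.
#' @param clamp admissible factor range; values outside are clamped with a
#'   warning (default `c(1, 5)`).
#' @param factor_fun optional replacement `function(r_iso_a, r_iso_b,
#'   r_state_a, r_state_b)` returning the factor.
#' @return Dimensionless factor (vectorised over `a`, `b`).
#' @export
adjustment_factor <- function(ranges, a, b, state = c("isothermal", "stratified"),
                              clamp = c(1, 5), factor_fun = NULL) {
  state <- match.arg(state)
  assert_cols(ranges, c("station_id", "range_iso_m", "range_strat_m"),
              "detection ranges")
  if (any(ranges$range_iso_m <= 0) || any(ranges$range_strat_m <= 0))
    stopf("detection ranges must be positive")
  ia <- match(a, ranges$station_id); ib <- match(b, ranges$station_id)
  if (anyNA(ia) || anyNA(ib))
    stopf("station(s) missing from the range table: %s",
          paste(unique(c(a[is.na(ia)], b[is.na(ib)])), collapse = ", "))
  rs <- if (state == "isothermal") "range_iso_m" else "range_strat_m"
  f <- if (is.null(factor_fun)) {
    (ranges$range_iso_m[ia] + ranges$range_iso_m[ib]) /
      (ranges[[rs]][ia] + ranges[[rs]][ib])
  } else {
    factor_fun(ranges$range_iso_m[ia], ranges$range_iso_m[ib],
               ranges[[rs]][ia], ranges[[rs]][ib])
  }
  if (any(f < clamp[1] | f > clamp[2])) {
    warnf("%d adjustment factor(s) clamped to [%g, %g]",
          sum(f < clamp[1] | f > clamp[2]), clamp[1], clamp[2])
    f <- pmin(pmax(f, clamp[1]), clamp[2])
  }
  f
}

#' Station-pair table: least-cost distance plus adjustment factors
#'
#' @param mask a [water_mask()].
#' @param stations station table with `station_id`, `x`, `y`, `range_iso_m`,
#'   `range_strat_m`.
#' @param tolerance snap radius in cells.
#' @inheritParams adjustment_factor
#' @return Data frame with one row per unordered station pair:
#'   `station_a`, `station_b`, `least_cost_m`, `factor_isothermal` (all 1),
#'   `factor_stratified`.
#' @export
station_pairs <- function(mask, stations, tolerance = 3, clamp = c(1, 5),
                          factor_fun = NULL) {
  d <- least_cost_distances(mask, stations, tolerance)
  ids <- rownames(d)
  pr <- which(upper.tri(d), arr.ind = TRUE)
  out <- data.frame(station_a = ids[pr[, 1]], station_b = ids[pr[, 2]],
                    least_cost_m = d[pr])
  out$factor_isothermal <- adjustment_factor(stations, out$station_a,
                                             out$station_b, "isothermal",
                                             clamp, factor_fun)
  out$factor_stratified <- adjustment_factor(stations, out$station_a,
                                             out$station_b, "stratified",
                                             clamp, factor_fun)
  out
}

#' Classify months as stratified or isothermal
#'
#' A month is stratified when the mean daily surface-to-bottom temperature
#' difference exceeds `threshold_c` (default 1 degree C).
#'
#' @param daily aggregated daily profiles ([aggregate_daily_profiles()]).
#' @param threshold_c temperature-difference threshold, degrees C.
#' @return Data frame `year`, `month`, `delta_t_c`, `state`.
#' @export
classify_stratification_state <- function(daily, threshold_c = 1) {
  assert_cols(daily, c("date", "stratum", "temp_c"), "daily profiles")
  if (nrow(daily) == 0L) stopf("no profile data")
  daily$date <- as.Date(daily$date)
  per_day <- split(daily, daily$date)
  dd <- do.call(rbind, lapply(per_day, function(d) {
    data.frame(date = d$date[1L],
               dt = d$temp_c[which.min(d$stratum)] -
                    d$temp_c[which.max(d$stratum)])
  }))
  yr <- as.integer(format(dd$date, "%Y"))
  mo <- as.integer(format(dd$date, "%m"))
  out <- do.call(rbind, lapply(split(dd$dt, paste(yr, mo, sep = "-")),
                               function(x) data.frame(delta_t_c = mean(x))))
  parts <- do.call(rbind, strsplit(rownames(out), "-"))
  out <- data.frame(year = as.integer(parts[, 1]), month = as.integer(parts[, 2]),
                    delta_t_c = out$delta_t_c)
  out$state <- ifelse(out$delta_t_c > threshold_c, "stratified", "isothermal")
  out <- out[order(out$year, out$month), ]
  rownames(out) <- NULL
  out
}
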