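# Independent oracles and small fixture builders used across the suite.

# Brute-force Dijkstra over an 8-connected water mask (plain O(n^2) scan,
# independent of the package's graph-based implementation). mask: logical
# matrix; from/to: c(row, col); returns metres.
brute_dijkstra <- function(mask, cell_size, from, to) {
  nr <- nrow(mask); nc <- ncol(mask)
  dist <- matrix(Inf, nr, nc)
  done <- matrix(FALSE, nr, nc)
  dist[from[1], from[2]] <- 0
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  w <- ifelse(abs(offs[, 1]) + abs(offs[, 2]) == 2, cell_size * sqrt(2), cell_size)
  repeat {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0L) break
    u <- cand[which.min(dist[cand])]
    ur <- ((u - 1L) %% nr) + 1L; uc <- ((u - 1L) %/% nr) + 1L
    done[ur, uc] <- TRUE
    if (ur == to[1] && uc == to[2]) return(dist[ur, uc])
    for (k in 1:8) {
      r2 <- ur + offs[k, 1]; c2 <- uc + offs[k, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!mask[r2, c2]) next
      nd <- dist[ur, uc] + w[k]
      if (nd < dist[r2, c2]) dist[r2, c2] <- nd
    }
  }
  dist[to[1], to[2]]
}

# analytic volume of a radial power-law bowl depth = D * (1 - (rho/R)^p):
# V = integral_0^D pi R^2 (1 - d/D)^(2/p) dd = pi R^2 D * p / (p + 2)
bowl_volume <- function(R, D, p) pi * R^2 * D * p / (p + 2)

# analytic stratum areas for the same bowl: A(d) = pi R^2 (1 - d/D)^(2/p)
bowl_area <- function(d, R, D, p) pi * R^2 * pmax(0, 1 - d / D)^(2 / p)

# detections data frame from a station-visit sequence at a fixed spacing
make_detections <- function(visits, transmitter = "F01", spacing = 300,
                            start = as.POSIXct("2017-06-01 00:00:00", tz = "UTC")) {
  data.frame(detection_timestamp_utc = start + seq_along(visits) * spacing,
             transmitter_id = transmitter,
             receiver_sn = as.character(visits))
}

# one-day profile data frame covering n strata
make_profile <- function(date, temp, do, depths = seq_along(temp) - 1) {
  data.frame(date = as.Date(date), depth_m = depths, temp_c = temp, do_mgl = do)
}

# hand-sum displacement over an edge list (enumeration oracle)
sum_displacement <- function(edges, pairs, fcol) {
  total <- 0
  for (i in seq_len(nrow(edges))) {
    j <- which((pairs$station_a == edges$station_a[i] &
                pairs$station_b == edges$station_b[i]) |
               (pairs$station_a == edges$station_b[i] &
                pairs$station_b == edges$station_a[i]))
    total <- total + edges$weight[i] * pairs[[fcol]][j] * pairs$least_cost_m[j]
  }
  total / 1000
}

# small shared synthetic study, computed once per test run
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_study(lake_scenario(n_fish = 4, seed = 7),
                               year = 2017, months = 6:8)
    cache
  }
})
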