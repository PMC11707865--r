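#' Build a movement network for one fish-month
#'
#' Nodes are receiver stations; each consecutive pair of detections at
#' *different* stations adds one movement to that (undirected) pair's edge
#' weight; consecutive detections at the same station contribute nothing.
#' Input detections should already be QC-filtered and the fish-month should
#' have passed the residency filter.
#'
#' @param detections detections for a single transmitter and month
#'   (`detection_timestamp_utc`, `receiver_sn`).
#' @param fish,month,year metadata stored on the network (derived from the
#'   data when omitted).
#' @return An object of class `movement_network`: list with `fish`, `month`,
#'   `year`, `visits` (the chronological station sequence), `edges` (data
#'   frame `station_a`, `station_b`, `weight`), `n_moves`. Fewer than 2
#'   detections yield an empty, flagged network.
#' @export
build_network <- function(detections, fish = NULL, month = NULL, year = NULL) {
  detections <- check_detections(detections)
  detections <- detections[order(detections$detection_timestamp_utc), ]
  fish <- fish %||% unique(detections$transmitter_id)[1]
  if (nrow(detections)) {
    month <- month %||%
      as.integer(format(detections$detection_timestamp_utc[1], "%m"))
    year <- year %||%
      as.integer(format(detections$detection_timestamp_utc[1], "%Y"))
  }
  visits <- as.character(detections$receiver_sn)
  net <- list(fish = fish, month = month, year = year, visits = visits)
  if (length(visits) < 2L) {
    net$edges <- data.frame(station_a = character(), station_b = character(),
                            weight = integer())
    net$n_moves <- 0L
    net$empty <- TRUE
    class(net) <- "movement_network"
    return(net)
  }
  net$edges <- edges_from_visits(visits)
  net$n_moves <- sum(net$edges$weight)
  net$empty <- nrow(net$edges) == 0L
  class(net) <- "movement_network"
  net
}

# undirected edge table from a chronological station sequence
edges_from_visits <- function(visits) {
  a <- visits[-length(visits)]
  b <- visits[-1L]
  mv <- a != b
  if (!any(mv))
    return(data.frame(station_a = character(), station_b = character(),
                      weight = integer()))
  lo <- pmin(a[mv], b[mv])
  hi <- pmax(a[mv], b[mv])
  tab <- table(paste(lo, hi, sep = "\r"))
  parts <- do.call(rbind, strsplit(names(tab), "\r"))
  out <- data.frame(station_a = parts[, 1], station_b = parts[, 2],
                    weight = as.integer(tab))
  out[order(out$station_a, out$station_b), , drop = FALSE]
}

#' @export
print.movement_network <- function(x, ...) {
  cat(sprintf("movement network: fish %s, %04d-%02d; %d visits, %d moves, %d edges\n",
              x$fish, x$year %||% NA, x$month %||% NA, length(x$visits),
              x$n_moves, nrow(x$edges)))
  invisible(x)
}

#' Convert a movement network to an igraph object
#' @param net a `movement_network`.
#' @return A weighted undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = net$edges$station_a, to = net$edges$station_b,
               weight = net$edges$weight),
    directed = FALSE,
    vertices = data.frame(name = unique(net$visits)))
}

#' Permutation test of a movement network against random networks
#'
#' Null networks are generated by uniformly shuffling the fish's
#' chronological station-visit sequence (preserving the multiset of visited
#' stations) and rebuilding the edge list. The test statistic is the number
#' of distinct edges; the two-sided permutation p-value uses the add-one
#' correction `p = (1 + #[null as or more extreme]) / (n_perm + 1)`, with
#' extremeness measured as absolute deviation from the null mean. The
#' statistic and null are a reconstruction (the published construction is in
#' unavailable supplementary material); both can be replaced via `stat_fun`.
#'
#' @param net a `movement_network`.
#' @param n_perm number of permutations (default 1000).
#' @param alpha significance level (default 0.05; significant iff
#'   `p <= alpha`).
#' @param seed optional integer seed for the shuffles.
#' @param stat_fun function(edge data frame) -> scalar statistic; default
#'   counts distinct edges.
#' @return List of class `network_significance`: `observed`, `null_mean`,
#'   `null_sd`, `p_value`, `significant`, `n_perm`, `alpha`, `statistic`
#'   label. Degenerate single-station sequences return `p_value = NA` and
#'   `significant = FALSE` (network dropped downstream).
#' @export
random_network_test <- function(net, n_perm = 1000, alpha = 0.05, seed = NULL,
                                stat_fun = NULL) {
  if (!inherits(net, "movement_network")) stopf("net must be a movement_network")
  stat_fun <- stat_fun %||% nrow
  if (length(net$visits) < 2L || length(unique(net$visits)) < 2L) {
    return(structure(list(observed = NA_real_, null_mean = NA_real_,
                          null_sd = NA_real_, p_value = NA_real_,
                          significant = FALSE, n_perm = n_perm, alpha = alpha,
                          statistic = "n_distinct_edges",
                          degenerate = TRUE),
                     class = "network_significance"))
  }
  obs <- stat_fun(net$edges)
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      stat_fun(edges_from_visits(sample(net$visits)))
    }, numeric(1))
  })
  mu <- mean(null_stats)
  p <- (1 + sum(abs(null_stats - mu) >= abs(obs - mu))) / (n_perm + 1)
  structure(list(observed = obs, null_mean = mu, null_sd = stats::sd(null_stats),
                 p_value = p, significant = p <= alpha, n_perm = n_perm,
                 alpha = alpha, statistic = "n_distinct_edges",
                 degenerate = FALSE),
            class = "network_significance")
}

#' Seasonally adjusted displacement distance of a network
#'
#' For every edge, multiplies the number of movements by the stratification
#' state's detection-range adjustment factor and by the in-water least-cost
#' distance between the pair, then totals over edges:
#' `displacement_km = sum(weight * factor(state) * least_cost_m) / 1000`.
#'
#' @param net a `movement_network`.
#' @param pairs station-pair table from [station_pairs()].
#' @param state `"isothermal"` or `"stratified"` for this fish-month.
#' @return One-row data frame: `transmitter_id`, `year`, `month`,
#'   `displacement_km`, `state`, `n_edges`, `n_moves`.
#' @export
displacement_distance <- function(net, pairs,
                                  state = c("isothermal", "stratified")) {
  state <- match.arg(state)
  assert_cols(pairs, c("station_a", "station_b", "least_cost_m",
                       "factor_isothermal", "factor_stratified"),
              "station pairs")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  pk <- key(pairs$station_a, pairs$station_b)
  fcol <- if (state == "isothermal") "factor_isothermal" else "factor_stratified"
  i <- match(key(net$edges$station_a, net$edges$station_b), pk)
  if (anyNA(i)) {
    bad <- net$edges[is.na(i), c("station_a", "station_b")]
    stopf("no station-pair entry for: %s",
          paste(paste(bad$station_a, bad$station_b, sep = "-"), collapse = ", "))
  }
  km <- sum(net$edges$weight * pairs[[fcol]][i] * pairs$least_cost_m[i]) / 1000
  data.frame(transmitter_id = net$fish, year = net$year, month = net$month,
             displacement_km = km, state = state, n_edges = nrow(net$edges),
             n_moves = net$n_moves)
}

#' Pool path weights across networks for mapping
#'
#' Sums edge weights over networks within each month (across fish and
#' years), attaching node coordinates when a station table is supplied —
#' the data behind a monthly movement map.
#'
#' @param networks list of `movement_network`s (typically those that passed
#'   [random_network_test()]).
#' @param stations optional station table with `station_id`, `x`, `y`.
#' @return Data frame `month`, `station_a`, `station_b`, `weight` (+
#'   coordinates `xa`, `ya`, `xb`, `yb` when stations given). Empty input
#'   yields an empty table.
#' @export
export_path_weights <- function(networks, stations = NULL) {
  if (length(networks) == 0L)
    return(data.frame(month = integer(), station_a = character(),
                      station_b = character(), weight = integer()))
  tabs <- lapply(networks, function(n) {
    if (nrow(n$edges) == 0L) return(NULL)
    cbind(month = n$month, n$edges)
  })
  tab <- do.call(rbind, tabs)
  if (is.null(tab))
    return(data.frame(month = integer(), station_a = character(),
                      station_b = character(), weight = integer()))
  key <- paste(tab$month, tab$station_a, tab$station_b, sep = "\r")
  w <- tapply(tab$weight, key, sum)
  parts <- do.call(rbind, strsplit(names(w), "\r"))
  out <- data.frame(month = as.integer(parts[, 1]), station_a = parts[, 2],
                    station_b = parts[, 3], weight = as.integer(w))
  out <- out[order(out$month, out$station_a, out$station_b), ]
  rownames(out) <- NULL
  if (!is.null(stations)) {
    ia <- match(out$station_a, stations$station_id)
    ib <- match(out$station_b, stations$station_id)
    out$xa <- stations$x[ia]; out$ya <- stations$y[ia]
    out$xb <- stations$x[ib]; out$yb <- stations$y[ib]
  }
  out
}

#' Build, test and measure all fish-month networks
#'
#' Convenience driver: splits detections by transmitter, year and month,
#' keeps the fish-months listed in `eligible` (the residency filter output),
#' builds each network, applies the permutation test, and computes the
#' adjusted displacement of the significant networks.
#'
#' @param detections QC-filtered detections.
#' @param eligible eligible fish-months ([residency_filter()]).
#' @param pairs station-pair table ([station_pairs()]).
#' @param states month-state table ([classify_stratification_state()]).
#' @param months months to process (default April-November).
#' @param n_perm,alpha,seed passed to [random_network_test()].
#' @return List with `networks` (all built networks), `significance`
#'   (per-network test results), and `displacement` (data frame for the
#'   significant, non-degenerate networks).
#' @export
movement_analysis <- function(detections, eligible, pairs, states,
                              months = 4:11, n_perm = 1000, alpha = 0.05,
                              seed = NULL) {
  detections <- check_detections(detections)
  yr <- as.integer(format(detections$detection_timestamp_utc, "%Y"))
  mo <- as.integer(format(detections$detection_timestamp_utc, "%m"))
  keep <- mo %in% months
  detections <- detections[keep, ]; yr <- yr[keep]; mo <- mo[keep]
  ek <- paste(eligible$transmitter_id, eligible$year, eligible$month, sep = "\r")
  dk <- paste(detections$transmitter_id, yr, mo, sep = "\r")
  sk <- paste(states$year, states$month, sep = "\r")
  groups <- split(seq_len(nrow(detections)), dk)
  groups <- groups[names(groups) %in% ek]

  networks <- list(); signif <- list(); disp <- list()
  for (g in names(groups)) {
    parts <- strsplit(g, "\r")[[1]]
    net <- build_network(detections[groups[[g]], ], fish = parts[1],
                         month = as.integer(parts[3]),
                         year = as.integer(parts[2]))
    networks[[g]] <- net
    sig <- random_network_test(net, n_perm = n_perm, alpha = alpha,
                               seed = if (is.null(seed)) NULL
                                      else seed + length(networks))
    signif[[g]] <- sig
    if (isTRUE(sig$significant)) {
      st <- states$state[match(paste(parts[2], parts[3], sep = "\r"), sk)]
      if (is.na(st)) st <- "isothermal"
      d <- displacement_distance(net, pairs, st)
      d$p_value <- sig$p_value
      disp[[g]] <- d
    }
  }
  sig_df <- do.call(rbind, lapply(names(signif), function(g) {
    s <- signif[[g]]
    parts <- strsplit(g, "\r")[[1]]
    data.frame(transmitter_id = parts[1], year = as.integer(parts[2]),
               month = as.integer(parts[3]), observed = s$observed,
               p_value = s$p_value, significant = s$significant)
  }))
  disp_df <- if (length(disp)) do.call(rbind, disp) else
    data.frame(transmitter_id = character(), year = integer(),
               month = integer(), displacement_km = numeric(),
               state = character(), n_edges = integer(), n_moves = integer(),
               p_value = numeric())
  rownames(disp_df) <- NULL
  list(networks = networks, significance = sig_df, displacement = disp_df)
}
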