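# Fixtures are built in code; the brute-force routines here are the
# independent oracles the routing results are checked against.

# small connected network with cycles: points in a ~30 km box, each joined
# to its 3 nearest neighbours; every edge satisfies length >= straight line
tiny_network <- function(n = 10, seed = 42) {
  withr::with_seed(seed, {
    lat0 <- 50
    lat <- lat0 + runif(n, 0, 30) / 110.574
    lon <- -120 + runif(n, 0, 30) / (111.320 * cos(lat0 * pi / 180))
    ids <- sprintf("n%02d", seq_len(n))
    nodes <- tibble::tibble(id = ids, lat = lat, lon = lon)
    edges <- list()
    for (i in seq_len(n)) {
      d <- patientcost::haversine_km(lat[i], lon[i], lat, lon)
      nb <- order(d)[2:4]
      for (j in nb) {
        a <- min(i, j); b <- max(i, j)
        edges[[paste(a, b)]] <- tibble::tibble(
          u = ids[a], v = ids[b],
          length_km = patientcost::haversine_km(lat[a], lon[a], lat[b], lon[b]) *
            runif(1, 1.1, 1.5),
          speed_kmh = sample(c(50, 80), 1)
        )
      }
    }
    list(nodes = nodes, edges = dplyr::bind_rows(edges))
  })
}

# exhaustive enumeration of all simple paths; returns min total length,
# and the duration along that minimizing path
brute_force_shortest <- function(network, from, to) {
  edges <- network$edges
  both <- rbind(
    data.frame(a = edges$u, b = edges$v, len = edges$length_km, spd = edges$speed_kmh),
    data.frame(a = edges$v, b = edges$u, len = edges$length_km, spd = edges$speed_kmh)
  )
  adj <- split(both[c("b", "len", "spd")], both$a)
  best <- list(dist = Inf, dur = Inf)
  walk <- function(node, visited, dist, dur) {
    if (dist >= best$dist) return()
    if (node == to) {
      best <<- list(dist = dist, dur = dur)
      return()
    }
    nb <- adj[[node]]
    if (is.null(nb)) return()
    for (k in seq_len(nrow(nb))) {
      nxt <- nb$b[k]
      if (!(nxt %in% visited)) {
        walk(nxt, c(visited, nxt), dist + nb$len[k], dur + nb$len[k] / nb$spd[k] * 60)
      }
    }
  }
  walk(from, from, 0, 0)
  best
}

# independent nearest-facility search: snap by exhaustive scan, then take
# the facility minimizing the brute-force shortest-path distance
brute_force_nearest_facility <- function(lat, lon, facilities, network) {
  scan_snap <- function(plat, plon) {
    d <- patientcost::haversine_km(plat, plon, network$nodes$lat, network$nodes$lon)
    sort(network$nodes$id[d <= min(d) + 1e-12])[1]
  }
  src <- scan_snap(lat, lon)
  fac <- facilities[order(facilities$id), ]
  dists <- vapply(seq_len(nrow(fac)), function(i) {
    brute_force_shortest(network, src, scan_snap(fac$lat[i], fac$lon[i]))$dist
  }, 0)
  best <- which(dists <= min(dists) + 1e-9)[1]
  list(facility_id = fac$id[best], distance_km = dists[best])
}

# geography whose regions sit on top of the tiny network's nodes, used for
# routing-oracle and comparison tests
tiny_geography <- function() {
  net <- tiny_network()
  regions <- tibble::tibble(
    id = sprintf("T%02d", 1:4),
    name = paste("Tiny", 1:4),
    authority_id = c("A1", "A1", "A2", "A2"),
    class_code = c(2L, 3L, 5L, 6L),
    population = c(10000, 20000, 3000, 1500),
    lat = net$nodes$lat[c(1, 3, 6, 9)],
    lon = net$nodes$lon[c(1, 3, 6, 9)]
  )
  facilities <- tibble::tibble(
    id = c("F1", "F2"),
    lat = net$nodes$lat[c(2, 8)],
    lon = net$nodes$lon[c(2, 8)],
    kind = "emergency"
  )
  authorities <- tibble::tibble(id = c("A1", "A2"), name = c("Alpha", "Beta"))
  structure(
    list(regions = regions, authorities = authorities,
         facilities = facilities, network = net),
    class = "geography"
  )
}

# base-case urban/rural scopes using the published reference distances, with
# durations derived at typical driving speeds
reference_scopes <- function() {
  tibble::tibble(
    scope = c("urban", "rural"),
    distance_km = c(18.94, 91.2),
    duration_min = c(18.94 / 50 * 60, 91.2 / 70 * 60)
  )
}
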