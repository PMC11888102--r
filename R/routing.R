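EARTH_RADIUS_KM <- 6371

#' Great-circle (haversine) distance in kilometres
#'
#' Straight-line distance over the Earth's surface between two points in
#' WGS84 degrees, using a spherical Earth of radius 6371 km. Vectorized.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees.
#' @return distance(s) in km.
#' @export
#' @examples
#' haversine_km(49, -123, 49, -122) # ~73 km along the 49th parallel
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = FALSE) ||
      any(abs(c(lon1, lon2)) > 180)) {
    abort("coordinates out of range: |lat| <= 90, |lon| <= 180",
          class = "patientcost_invalid_argument")
  }
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Snap a point to the nearest road-network node
#'
#' Returns the node id minimizing the haversine distance to the point; ties
#' are broken by the lexicographically smallest node id.
#'
#' @param lat,lon point coordinates in degrees.
#' @param network road network (list with `nodes` and `edges`).
#' @return a node id (character scalar).
#' @export
snap_to_network <- function(lat, lon, network) {
  nodes <- network$nodes
  if (is.null(nodes) || nrow(nodes) == 0) {
    abort("cannot snap to an empty network", class = "patientcost_invalid_argument")
  }
  d <- haversine_km(lat, lon, nodes$lat, nodes$lon)
  cand <- nodes$id[d <= min(d) + 1e-12]
  sort(cand)[1]
}

network_graph <- function(network) {
  igraph::graph_from_data_frame(
    d = network$edges[, c("u", "v", "length_km", "speed_kmh")],
    directed = FALSE,
    vertices = network$nodes[, c("id", "lat", "lon")]
  )
}

#' Street route from a region centroid to its nearest facility
#'
#' Snaps the centroid and every facility to the road network and returns the
#' facility reachable by the minimum length-weighted shortest path; travel
#' duration is derived on that same path from per-edge speed limits as
#' sum(length / speed) * 60. Ties between equally near facilities are broken
#' by facility id.
#'
#' @param region a one-row region tibble (needs `id`, `lat`, `lon`).
#' @param facilities facility tibble (`id`, `lat`, `lon`).
#' @param network road network.
#' @param graph optionally, a prebuilt igraph of the network (for reuse).
#' @return one-row tibble: `region_id`, `facility_id`, `distance_km`,
#'   `duration_min`, `path` (list column of node ids).
#' @export
route_to_nearest_facility <- function(region, facilities, network, graph = NULL) {
  if (nrow(facilities) == 0) {
    abort("at least one facility is required", class = "patientcost_invalid_argument")
  }
  g <- graph %||% network_graph(network)
  src <- snap_to_network(region$lat, region$lon, network)
  fac <- dplyr::arrange(facilities, .data$id)
  fac$node <- vapply(
    seq_len(nrow(fac)),
    function(i) snap_to_network(fac$lat[i], fac$lon[i], network),
    ""
  )
  d <- igraph::distances(g, v = src, to = unique(fac$node),
                         weights = igraph::E(g)$length_km)
  fac$dist <- d[1, fac$node]
  if (all(!is.finite(fac$dist))) {
    abort(paste0("no facility reachable from region '", region$id, "'"),
          class = "patientcost_unreachable_error")
  }
  best <- fac[which(fac$dist <= min(fac$dist, na.rm = TRUE) + 1e-12), ][1, ]
  sp <- igraph::shortest_paths(g, from = src, to = best$node,
                               weights = igraph::E(g)$length_km, output = "both")
  ep <- sp$epath[[1]]
  dist_km <- sum(igraph::edge_attr(g, "length_km", ep))
  dur_min <- sum(igraph::edge_attr(g, "length_km", ep) /
                   igraph::edge_attr(g, "speed_kmh", ep)) * 60
  tibble(
    region_id = region$id,
    facility_id = best$id,
    distance_km = dist_km,
    duration_min = dur_min,
    path = list(names(sp$vpath[[1]]))
  )
}

#' Route every region to its nearest facility
#'
#' @param geography a `geography` object.
#' @return tibble with one row per region: `region_id`, `facility_id`,
#'   `distance_km`, `duration_min`, `path`.
#' @export
route_all_regions <- function(geography) {
  g <- network_graph(geography$network)
  purrr::map_dfr(
    seq_len(nrow(geography$regions)),
    function(i) route_to_nearest_facility(
      geography$regions[i, ], geography$facilities, geography$network, graph = g
    )
  )
}

#' Population-weighted mean
#'
#' @param values per-region values.
#' @param weights region populations (same length, sum > 0, none negative).
#' @return the weighted mean.
#' @export
population_weighted_mean <- function(values, weights) {
  if (length(values) != length(weights)) {
    abort("`values` and `weights` must have the same length",
          class = "patientcost_invalid_argument")
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    abort("weights must be non-negative with a positive sum",
          class = "patientcost_invalid_argument")
  }
  sum(values * weights) / sum(weights)
}

#' Split regions into urban and rural strata
#'
#' Region classes 1-4 are urban, 5-7 rural.
#'
#' @param regions region tibble with a `class_code` column.
#' @return list with tibbles `urban` and `rural`.
#' @export
stratify_urban_rural <- function(regions) {
  list(
    urban = dplyr::filter(regions, .data$class_code <= 4),
    rural = dplyr::filter(regions, .data$class_code >= 5)
  )
}

#' Aggregate per-region travel to authorities or urban/rural strata
#'
#' Population-weighted mean of street distance and duration over the member
#' regions of each grouping.
#'
#' @param travel output of [route_all_regions()].
#' @param regions region tibble.
#' @param by `"authority"` or `"stratum"` (urban/rural).
#' @return tibble: `scope`, `distance_km`, `duration_min`, `population`.
#' @export
aggregate_travel <- function(travel, regions, by = c("authority", "stratum")) {
  by <- match.arg(by)
  d <- dplyr::inner_join(travel, regions, by = c(region_id = "id"))
  d$scope <- if (by == "authority") d$authority_id else
    ifelse(d$class_code <= 4, "urban", "rural")
  d |>
    dplyr::group_by(.data$scope) |>
    dplyr::summarise(
      distance_km = population_weighted_mean(.data$distance_km, .data$population),
      duration_min = population_weighted_mean(.data$duration_min, .data$population),
      population = sum(.data$population),
      .groups = "drop"
    )
}

#' Compare street-routing distances with haversine distances
#'
#' For each region, the street distance to the nearest facility (by road) is
#' compared with the haversine distance to the nearest facility (straight
#' line). The summary counts regions whose two distances agree within
#' `threshold_km` and reports the largest amount by which the straight-line
#' method underestimates the street method.
#'
#' @param regions,facilities,network geography layers.
#' @param threshold_km agreement threshold in km (default 10).
#' @return list with `table` (per-region tibble: `region_id`, `street_km`,
#'   `haversine_km`, `difference_km`) and `summary` (list `n_within`,
#'   `n_beyond`, `max_underestimate_km`).
#' @export
compare_street_vs_haversine <- function(regions, facilities, network, threshold_km = 10) {
  g <- network_graph(network)
  rows <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    street <- route_to_nearest_facility(r, facilities, network, graph = g)
    hav <- min(haversine_km(r$lat, r$lon, facilities$lat, facilities$lon))
    tibble(
      region_id = r$id,
      street_km = street$distance_km,
      haversine_km = hav,
      difference_km = street$distance_km - hav
    )
  })
  list(
    table = rows,
    summary = list(
      n_within = sum(rows$difference_km <= threshold_km),
      n_beyond = sum(rows$difference_km > threshold_km),
      max_underestimate_km = if (nrow(rows) > 0) max(rows$difference_km) else 0
    )
  )
}
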