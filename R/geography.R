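# km of one degree of latitude / of longitude at latitude `lat`
KM_PER_DEG_LAT <- 110.574
km_per_deg_lon <- function(lat) 111.320 * cos(lat * pi / 180)

offset_point <- function(lat, lon, dist_km, bearing_rad) {
  # small-offset planar approximation, adequate at the scales generated here
  dlat <- dist_km * cos(bearing_rad) / KM_PER_DEG_LAT
  dlon <- dist_km * sin(bearing_rad) / km_per_deg_lon(lat)
  c(lat = lat + dlat, lon = lon + dlon)
}

new_geography <- function(regions, authorities, facilities, network) {
  structure(
    list(regions = regions, authorities = authorities,
         facilities = facilities, network = network),
    class = "geography"
  )
}

#' @export
print.geography <- function(x, ...) {
  cat(sprintf(
    "<geography> %d regions (%d urban / %d rural), %d authorities, %d facilities, network: %d nodes / %d edges\n",
    nrow(x$regions), sum(x$regions$class_code <= 4), sum(x$regions$class_code >= 5),
    nrow(x$authorities), nrow(x$facilities),
    nrow(x$network$nodes), nrow(x$network$edges)
  ))
  invisible(x)
}

validate_regions <- function(regions, authorities) {
  req <- c("id", "name", "authority_id", "class_code", "population", "lat", "lon")
  miss <- setdiff(req, names(regions))
  if (length(miss) > 0) {
    schema_error(paste0("region table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    if (is.na(r$class_code) || !r$class_code %in% 1:7) {
      schema_error(paste0("region '", r$id, "': class_code must be an integer 1-7"))
    }
    if (is.na(r$population) || r$population < 0) {
      schema_error(paste0("region '", r$id, "': population must be a non-negative count"))
    }
    if (is.na(r$lat) || abs(r$lat) > 90 || is.na(r$lon) || abs(r$lon) > 180) {
      validation_error(paste0(
        "region '", r$id, "': centroid must have latitude in [-90, 90] and longitude in [-180, 180]"
      ))
    }
    if (!r$authority_id %in% authorities$id) {
      abort(paste0("region '", r$id, "' references unknown authority '", r$authority_id, "'"),
            class = "patientcost_referential_error")
    }
  }
  invisible(regions)
}

validate_network <- function(network) {
  nodes <- network$nodes
  edges <- network$edges
  if (nrow(nodes) == 0) schema_error("road network has no nodes")
  if (any(abs(nodes$lat) > 90) || any(abs(nodes$lon) > 180)) {
    validation_error("network node coordinates out of range")
  }
  bad <- which(!(edges$length_km > 0))
  if (length(bad) > 0) {
    schema_error(paste0("network edge ", edges$u[bad[1]], "-", edges$v[bad[1]],
                        ": length_km must be > 0"))
  }
  bad <- which(!(edges$speed_kmh > 0))
  if (length(bad) > 0) {
    schema_error(paste0("network edge ", edges$u[bad[1]], "-", edges$v[bad[1]],
                        ": speed_kmh must be > 0"))
  }
  missing_nodes <- setdiff(c(edges$u, edges$v), nodes$id)
  if (length(missing_nodes) > 0) {
    abort(paste0("network edges reference unknown node(s): ",
                 paste(utils::head(missing_nodes, 3), collapse = ", ")),
          class = "patientcost_referential_error")
  }
  invisible(network)
}

# chain of nodes from a start node out to a target point, one node at most
# every `max_seg_km`; edge lengths are straight-line distance times a road
# circuity factor >= 1, so the network invariant
# length_km >= haversine(endpoints) holds by construction
build_spoke <- function(prefix, from_id, from_lat, from_lon, to_lat, to_lon,
                        speed_kmh, max_seg_km = 20) {
  total <- haversine_km(from_lat, from_lon, to_lat, to_lon)
  k <- max(1L, ceiling(total / max_seg_km))
  frac <- seq_len(k) / k
  lats <- from_lat + (to_lat - from_lat) * frac
  lons <- from_lon + (to_lon - from_lon) * frac
  ids <- paste0(prefix, "_", seq_len(k))
  prev_id <- from_id; prev_lat <- from_lat; prev_lon <- from_lon
  nodes <- tibble(id = ids, lat = lats, lon = lons)
  circuity <- 1.15 + 0.15 * stats::runif(k)
  edges <- tibble(
    u = c(from_id, ids[-k]),
    v = ids,
    length_km = NA_real_,
    speed_kmh = speed_kmh
  )
  seg <- haversine_km(c(from_lat, lats[-k]), c(from_lon, lons[-k]), lats, lons)
  edges$length_km <- pmax(seg, 1e-4) * circuity
  list(nodes = nodes, edges = edges)
}

#' Generate a deterministic synthetic geography
#'
#' Builds a small province-like test geography: a 3x3 road grid around a hub
#' hosting two emergency departments, urban regions (class 1-4) whose
#' centroids sit 0.6-15 km from the hub, and rural regions (class 5-7) at
#' the ends of long spokes 30-300 km out, so that nearest-facility street
#' distances span roughly three orders of magnitude, as they do across real
#' urban/rural health geographies. Every region centroid coincides with a
#' network node, the graph is connected, and every edge satisfies
#' `length_km >= ` straight-line distance between its endpoints.
#'
#' @param n_regions number of regions (>= 2).
#' @param urban_fraction fraction of regions given an urban class (class
#'   1-4); the rest are rural (class 5-7).
#' @param seed integer seed; output is identical for identical seeds.
#' @return a `geography`: list with tibbles `regions` (id, name,
#'   authority_id, class_code, population, lat, lon), `authorities` (id,
#'   name), `facilities` (id, lat, lon, kind), and `network` (list of
#'   `nodes` and `edges`).
#' @export
#' @examples
#' geo <- generate_synthetic_geography(n_regions = 6, urban_fraction = 0.5, seed = 1)
#' geo$regions$class_code
generate_synthetic_geography <- function(n_regions = 20, urban_fraction = 0.5, seed = 1) {
  if (!is.numeric(n_regions) || length(n_regions) != 1L || is.na(n_regions) || n_regions < 2) {
    abort("`n_regions` must be an integer >= 2", class = "patientcost_invalid_argument")
  }
  assert_number(urban_fraction, "urban_fraction", min = 0, max = 1)
  n_regions <- as.integer(n_regions)
  n_urban <- as.integer(round(n_regions * urban_fraction))
  n_rural <- n_regions - n_urban

  with_local_seed(seed, {
    hub_lat <- 54.0; hub_lon <- -125.0
    # 3x3 grid, 2 km spacing, rook adjacency; hub is the centre node G22
    offs <- c(-2, 0, 2)
    grid <- expand.grid(i = 1:3, j = 1:3)
    grid_nodes <- tibble(
      id = sprintf("G%d%d", grid$i, grid$j),
      lat = hub_lat + offs[grid$i] / KM_PER_DEG_LAT,
      lon = hub_lon + offs[grid$j] / km_per_deg_lon(hub_lat)
    )
    ge <- list()
    for (i in 1:3) for (j in 1:3) {
      if (j < 3) ge[[length(ge) + 1]] <- c(sprintf("G%d%d", i, j), sprintf("G%d%d", i, j + 1))
      if (i < 3) ge[[length(ge) + 1]] <- c(sprintf("G%d%d", i, j), sprintf("G%d%d", i + 1, j))
    }
    gu <- vapply(ge, `[`, "", 1L); gv <- vapply(ge, `[`, "", 2L)
    lu <- grid_nodes[match(gu, grid_nodes$id), ]; lv <- grid_nodes[match(gv, grid_nodes$id), ]
    grid_edges <- tibble(
      u = gu, v = gv,
      length_km = haversine_km(lu$lat, lu$lon, lv$lat, lv$lon) * 1.1,
      speed_kmh = 50
    )

    facilities <- tibble(
      id = c("F1", "F2"),
      lat = c(grid_nodes$lat[grid_nodes$id == "G22"], grid_nodes$lat[grid_nodes$id == "G11"]),
      lon = c(grid_nodes$lon[grid_nodes$id == "G22"], grid_nodes$lon[grid_nodes$id == "G11"]),
      kind = "emergency"
    )

    radii <- c(
      if (n_urban > 0) seq(0.6, 15, length.out = max(n_urban, 2))[seq_len(n_urban)],
      if (n_rural > 0) seq(30, 300, length.out = max(n_rural, 2))[seq_len(n_rural)]
    )
    is_urban <- c(rep(TRUE, n_urban), rep(FALSE, n_rural))
    angles <- stats::runif(n_regions, 0, 2 * pi)
    classes <- ifelse(is_urban,
                      1L + (seq_len(n_regions) - 1L) %% 4L,
                      5L + (seq_len(n_regions) - 1L) %% 3L)
    pops <- ifelse(is_urban,
                   round(stats::runif(n_regions, 20000, 80000)),
                   round(stats::runif(n_regions, 500, 8000)))

    authorities <- tibble(id = c("A1", "A2"), name = c("Coastal Authority", "Inland Authority"))

    nodes <- grid_nodes
    edges <- grid_edges
    regions <- vector("list", n_regions)
    for (k in seq_len(n_regions)) {
      ctr <- offset_point(hub_lat, hub_lon, radii[k], angles[k])
      spoke <- build_spoke(
        prefix = sprintf("S%02d", k), from_id = "G22",
        from_lat = hub_lat, from_lon = hub_lon,
        to_lat = ctr[["lat"]], to_lon = ctr[["lon"]],
        speed_kmh = if (is_urban[k]) 50 else 80
      )
      nodes <- bind_rows(nodes, spoke$nodes)
      edges <- bind_rows(edges, spoke$edges)
      regions[[k]] <- tibble(
        id = sprintf("R%02d", k),
        name = sprintf("%s Region %02d", if (is_urban[k]) "Urban" else "Rural", k),
        authority_id = if (k %% 2 == 1) "A1" else "A2",
        class_code = classes[k],
        population = pops[k],
        lat = ctr[["lat"]],
        lon = ctr[["lon"]]
      )
    }
    regions <- bind_rows(regions)

    geo <- new_geography(regions, authorities, facilities,
                         list(nodes = nodes, edges = edges))
    validate_regions(geo$regions, geo$authorities)
    validate_network(geo$network)
    geo
  })
}
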