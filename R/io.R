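# Geography I/O: regions and facilities as RFC 7946 GeoJSON FeatureCollections
# (coordinates ordered [longitude, latitude]), the road network as two CSVs
# (nodes: id,lat,lon; edges: u,v,length_km,speed_kmh) and authorities as a CSV.

geography_paths <- function(dir) {
  list(
    regions = file.path(dir, "regions.geojson"),
    facilities = file.path(dir, "facilities.geojson"),
    authorities = file.path(dir, "authorities.csv"),
    nodes = file.path(dir, "nodes.csv"),
    edges = file.path(dir, "edges.csv")
  )
}

feature <- function(geometry, properties) {
  list(type = "Feature", geometry = geometry, properties = properties)
}

point_geometry <- function(lat, lon) {
  list(type = "Point", coordinates = c(lon, lat))
}

write_feature_collection <- function(features, path) {
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
}

#' Write a geography to a directory
#'
#' Writes `regions.geojson`, `facilities.geojson`, `authorities.csv`,
#' `nodes.csv` and `edges.csv`. [read_geography()] restores the object
#' losslessly.
#'
#' @param geography a `geography` object.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_geography <- function(geography, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- geography_paths(dir)
  rg <- geography$regions
  region_features <- lapply(seq_len(nrow(rg)), function(i) {
    r <- rg[i, ]
    geom <- if ("boundary" %in% names(rg) && !is.null(r$boundary[[1]])) {
      ring <- r$boundary[[1]] # matrix with columns lat, lon
      list(type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)), function(k) c(ring[k, "lon"], ring[k, "lat"]))))
    } else {
      point_geometry(r$lat, r$lon)
    }
    feature(geom, list(
      id = r$id, name = r$name, authority_id = r$authority_id,
      class_code = r$class_code, population = r$population
    ))
  })
  write_feature_collection(region_features, p$regions)
  fc <- geography$facilities
  facility_features <- lapply(seq_len(nrow(fc)), function(i) {
    f <- fc[i, ]
    feature(point_geometry(f$lat, f$lon), list(id = f$id, kind = f$kind))
  })
  write_feature_collection(facility_features, p$facilities)
  utils::write.csv(geography$authorities, p$authorities, row.names = FALSE)
  utils::write.csv(geography$network$nodes, p$nodes, row.names = FALSE)
  utils::write.csv(geography$network$edges, p$edges, row.names = FALSE)
  invisible(dir)
}

# planar shoelace centroid of a polygon ring given as a matrix with
# columns lat, lon (adequate for the small-area polygons handled here)
polygon_centroid <- function(ring) {
  x <- ring[, "lon"]; y <- ring[, "lat"]
  n <- length(x)
  if (x[1] != x[n] || y[1] != y[n]) { x <- c(x, x[1]); y <- c(y, y[1]); n <- n + 1 }
  cross <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) return(c(lat = mean(y[-n]), lon = mean(x[-n])))
  c(lat = sum((y[-n] + y[-1]) * cross) / (6 * a),
    lon = sum((x[-n] + x[-1]) * cross) / (6 * a))
}

prop_or_schema_error <- function(props, key, id_hint) {
  if (is.null(props[[key]])) {
    schema_error(paste0("feature '", id_hint, "' is missing property '", key, "'"))
  }
  props[[key]]
}

#' Read a geography from a directory
#'
#' Inverse of [write_geography()]. Region features may be Points or
#' Polygons; for a Polygon the region centroid is its geometric centroid.
#' Records failing the schema (missing `class_code` or `population`, an
#' unknown `authority_id`, out-of-range coordinates, non-positive edge
#' length or speed) raise a classed error naming the offending record.
#'
#' @param dir directory written by [write_geography()].
#' @return a `geography` object.
#' @export
read_geography <- function(dir) {
  p <- geography_paths(dir)
  for (f in unlist(p)) {
    if (!file.exists(f)) schema_error(paste0("missing geography file: ", f))
  }
  authorities <- as_tibble(utils::read.csv(p$authorities, colClasses = "character"))

  rj <- jsonlite::read_json(p$regions)
  regions <- purrr::map_dfr(rj$features, function(ft) {
    props <- ft$properties
    id <- props$id %||% "<no id>"
    geom <- ft$geometry
    if (identical(geom$type, "Polygon")) {
      ring <- do.call(rbind, lapply(geom$coordinates[[1]], function(c2) {
        c(lat = c2[[2]], lon = c2[[1]])
      }))
      ctr <- polygon_centroid(ring)
      lat <- ctr[["lat"]]; lon <- ctr[["lon"]]
      boundary <- list(ring)
    } else {
      lon <- geom$coordinates[[1]]; lat <- geom$coordinates[[2]]
      boundary <- list(NULL)
    }
    tibble(
      id = id,
      name = prop_or_schema_error(props, "name", id),
      authority_id = prop_or_schema_error(props, "authority_id", id),
      class_code = as.integer(prop_or_schema_error(props, "class_code", id)),
      population = as.numeric(prop_or_schema_error(props, "population", id)),
      lat = lat, lon = lon,
      boundary = boundary
    )
  })
  if (all(vapply(regions$boundary, is.null, TRUE))) regions$boundary <- NULL

  fj <- jsonlite::read_json(p$facilities)
  facilities <- purrr::map_dfr(fj$features, function(ft) {
    props <- ft$properties
    tibble(
      id = props$id %||% schema_error("facility feature missing 'id'"),
      lat = ft$geometry$coordinates[[2]],
      lon = ft$geometry$coordinates[[1]],
      kind = props$kind %||% "emergency"
    )
  })
  if (any(abs(facilities$lat) > 90) || any(abs(facilities$lon) > 180)) {
    validation_error("facility coordinates out of range (is the file [lon, lat] ordered?)")
  }

  nodes <- as_tibble(utils::read.csv(p$nodes, colClasses = c(id = "character")))
  edges <- as_tibble(utils::read.csv(p$edges, colClasses = c(u = "character", v = "character")))
  network <- list(nodes = nodes, edges = edges)

  geo <- new_geography(regions, authorities, facilities, network)
  validate_regions(geo$regions, geo$authorities)
  validate_network(geo$network)
  geo
}
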