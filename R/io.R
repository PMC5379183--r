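#' Read geotagged events from CSV
#'
#' Expects columns `event_id,user_id,lat,lon` and optionally `timestamp`
#' (extra columns are ignored). Rows with out-of-range coordinates or missing
#' fields are dropped with a warning; duplicate event ids keep the first
#' occurrence. Rows without an `event_id` are deduplicated on the exact
#' `(user_id, lat, lon, timestamp)` tuple instead.
#'
#' @param path Path to a CSV file with a header row.
#' @return `data.frame` with columns `event_id`, `user_id`, `lat`, `lon`,
#'   `timestamp` (NA where absent).
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("event_id", "user_id", "lat", "lon")
  # event_id may be absent entirely; then dedup falls back to the tuple key
  core <- c("user_id", "lat", "lon")
  if (!all(core %in% names(df))) {
    stop("events CSV missing required column(s): ",
         paste(setdiff(core, names(df)), collapse = ", "))
  }
  if (!"event_id" %in% names(df)) df$event_id <- NA_character_
  if (!"timestamp" %in% names(df)) df$timestamp <- NA_character_
  if (nrow(df) == 0) {
    warning("events file is empty")
    return(df[, c(needed, "timestamp")])
  }
  df$lat <- suppressWarnings(as.numeric(df$lat))
  df$lon <- suppressWarnings(as.numeric(df$lon))
  ok <- !is.na(df$lat) & !is.na(df$lon) &
    df$lat >= -90 & df$lat <= 90 & df$lon >= -180 & df$lon <= 180 &
    nzchar(df$user_id)
  if (any(!ok)) {
    warning(sum(!ok), " malformed event row(s) dropped")
    df <- df[ok, , drop = FALSE]
  }
  key <- ifelse(is.na(df$event_id) | !nzchar(df$event_id),
                paste(df$user_id, df$lat, df$lon, df$timestamp, sep = "\r"),
                df$event_id)
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate event(s) dropped (first kept)")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df[, c(needed, "timestamp")]
}

#' Read location seeds from CSV
#'
#' Expects columns `location_id,lat,lon`.
#'
#' @param path Path to a CSV file with a header row.
#' @return `data.frame` with columns `location_id`, `lat`, `lon`.
#' @export
read_locations <- function(path) {
  if (!file.exists(path)) stop("locations file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(location_id = "character"))
  needed <- c("location_id", "lat", "lon")
  if (!all(needed %in% names(df))) {
    stop("locations CSV missing required column(s): ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  }
  if (anyDuplicated(df$location_id)) stop("duplicate location_id in seed table")
  bad <- df$lat < -90 | df$lat > 90 | df$lon < -180 | df$lon > 180
  if (any(bad)) stop("location(s) with out-of-range coordinates")
  df[, needed]
}

#' Assign events to their nearest seed location
#'
#' Each event is mapped to the location minimising great-circle distance
#' (spherical haversine); ties break towards the lexicographically smallest
#' `location_id`, so the assignment is deterministic and independent of seed
#' order.
#'
#' @param events `data.frame` from [read_events()] (needs `event_id`,
#'   `user_id`, `lat`, `lon`).
#' @param locations `data.frame` from [read_locations()].
#' @return `data.frame` with columns `event_id`, `user_id`, `location_id`.
#' @export
assign_events_to_locations <- function(events, locations) {
  if (nrow(locations) == 0) stop("locations table is empty")
  loc <- locations[order(locations$location_id), , drop = FALSE]
  if (nrow(events) == 0) {
    return(data.frame(event_id = character(), user_id = character(),
                      location_id = character(), stringsAsFactors = FALSE))
  }
  # distance from every event to every seed, in blocks to bound memory
  n <- nrow(events)
  idx <- integer(n)
  block <- 20000L %/% max(1L, nrow(loc)) + 1L
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(n, start + block - 1L)
    d <- outer(seq_along(rows), seq_len(nrow(loc)), function(i, j) {
      haversine_km(events$lat[rows[i]], events$lon[rows[i]],
                   loc$lat[j], loc$lon[j])
    })
    # ties: first (= smallest location_id, loc is sorted)
    idx[rows] <- max.col(-d, ties.method = "first")
  }
  data.frame(event_id = events$event_id,
             user_id = events$user_id,
             location_id = loc$location_id[idx],
             stringsAsFactors = FALSE)
}

#' Write boundary segments as GeoJSON
#'
#' Writes a `FeatureCollection` of `LineString` features, one per boundary
#' segment, each carrying a numeric `scale` property. Coordinates are
#' `[lon, lat]` per the GeoJSON convention.
#'
#' @param boundaries `data.frame` with columns `lon1`, `lat1`, `lon2`, `lat2`
#'   and `scale` (as produced by [extract_boundaries()] plus a scale column).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_boundaries_geojson <- function(boundaries, path) {
  feats <- lapply(seq_len(nrow(boundaries)), function(i) {
    b <- boundaries[i, ]
    list(
      type = "Feature",
      geometry = list(
        type = "LineString",
        coordinates = list(c(b$lon1, b$lat1), c(b$lon2, b$lat2))
      ),
      properties = list(scale = b$scale)
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read boundary segments back from GeoJSON
#'
#' Inverse of [write_boundaries_geojson()]; used for round-trip checks and to
#' resume a pipeline from disk.
#'
#' @param path GeoJSON file written by [write_boundaries_geojson()].
#' @return `data.frame` with columns `lon1`, `lat1`, `lon2`, `lat2`, `scale`.
#' @export
read_boundaries_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(fc$features) == 0) {
    return(data.frame(lon1 = numeric(), lat1 = numeric(), lon2 = numeric(),
                      lat2 = numeric(), scale = numeric()))
  }
  rows <- lapply(fc$features, function(f) {
    cc <- f$geometry$coordinates
    data.frame(lon1 = cc[[1]][[1]], lat1 = cc[[1]][[2]],
               lon2 = cc[[2]][[1]], lat2 = cc[[2]][[2]],
               scale = f$properties$scale)
  })
  do.call(rbind, rows)
}

#' Serialise / deserialise a movement graph as an edge-list CSV
#'
#' The documented dialect is `u,v,weight,distance_km`, one row per undirected
#' edge with `u < v`. Isolated vertices are carried in a `# vertex:` comment
#' block so a round trip is lossless.
#'
#' @param graph A [movement_graph] object.
#' @param path File path.
#' @return `path` (write) or a `movement_graph` (read).
#' @export
write_graph_csv <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  iso <- setdiff(graph$vertices, unique(c(graph$edges$u, graph$edges$v)))
  for (v in iso) writeLines(paste0("# vertex: ", v), con)
  write.csv(graph$edges, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_graph_csv
#' @export
read_graph_csv <- function(path) {
  lines <- readLines(path)
  isov <- sub("^# vertex: ", "", grep("^# vertex: ", lines, value = TRUE))
  edges <- read.csv(text = lines, comment.char = "#",
                    colClasses = c(u = "character", v = "character"))
  movement_graph(edges, vertices = union(isov, c(edges$u, edges$v)))
}
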