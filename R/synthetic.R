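#' Generate a synthetic world with planted scale structure
#'
#' Lays out locations with two levels of ground truth: `n_regions` region
#' centres on a coarse lattice, `towns_per_region` town centres ringed around
#' each region centre, and `locations_per_town` locations scattered uniformly
#' in a disc around each town centre. Local geometry is generated on a plane
#' in km and converted to small lon-lat offsets around a reference point, so
#' haversine distances reproduce the planted distances to well under 1%.
#' The defaults separate the three distance regimes (intra-town, intra-region,
#' inter-region) by factors of at least 5, which is what makes the planted
#' scales recoverable.
#'
#' @param n_regions Number of regions (default 2).
#' @param towns_per_region Towns per region (default 3).
#' @param locations_per_town Locations per town (default 15).
#' @param region_spacing_km Distance between adjacent region centres
#'   (default 200).
#' @param town_spacing_km Radius of the town ring inside a region
#'   (default 20).
#' @param town_radius_km Radius of the location disc inside a town
#'   (default 2).
#' @param seed Integer seed; the same seed reproduces coordinates exactly.
#' @param origin `c(lat, lon)` reference point (default c(50, 8)).
#' @return Object of class `"planted_world"`: `locations` (`location_id`,
#'   `lat`, `lon`, `region`, `town`), the generator parameters, and `seed`.
#' @export
generate_world <- function(n_regions = 2L, towns_per_region = 3L,
                           locations_per_town = 15L,
                           region_spacing_km = 200, town_spacing_km = 20,
                           town_radius_km = 2, seed = 1L,
                           origin = c(50, 8)) {
  # consecutive-level separation: region centre spacing >> inter-town centre
  # spacing >> intra-town extent, each by a factor of at least 5
  town_gap <- if (towns_per_region > 1) {
    2 * town_spacing_km * sin(pi / towns_per_region)
  } else town_spacing_km
  if (region_spacing_km < 5 * town_gap || town_gap < 5 * 2 * town_radius_km) {
    stop("infeasible spacing: need >= 5x separation between consecutive levels")
  }
  set.seed(derive_seed(seed, 1L))
  rows <- list()
  for (r in seq_len(n_regions)) {
    # region centres on a line; towns on a ring with angular jitter
    rc <- c((r - 1) * region_spacing_km, 0)
    for (t in seq_len(towns_per_region)) {
      ang <- 2 * pi * (t - 1) / towns_per_region +
        stats::runif(1, -0.2, 0.2)
      tc <- rc + town_spacing_km * c(cos(ang), sin(ang))
      rad <- town_radius_km * sqrt(stats::runif(locations_per_town))
      th <- stats::runif(locations_per_town, 0, 2 * pi)
      rows[[length(rows) + 1L]] <- data.frame(
        x = tc[1] + rad * cos(th),
        y = tc[2] + rad * sin(th),
        region = r,
        town = (r - 1L) * towns_per_region + t
      )
    }
  }
  pts <- do.call(rbind, rows)
  km_per_deg <- 6371.0088 * pi / 180
  pts$lat <- origin[1] + pts$y / km_per_deg
  pts$lon <- origin[2] + pts$x / (km_per_deg * cos(origin[1] * pi / 180))
  pts$location_id <- sprintf("L%03d", seq_len(nrow(pts)))
  structure(list(
    locations = pts[, c("location_id", "lat", "lon", "region", "town")],
    n_regions = n_regions, towns_per_region = towns_per_region,
    locations_per_town = locations_per_town,
    region_spacing_km = region_spacing_km,
    town_spacing_km = town_spacing_km, town_radius_km = town_radius_km,
    seed = seed
  ), class = "planted_world")
}

#' @export
print.planted_world <- function(x, ...) {
  cat(sprintf("Planted world: %d regions x %d towns x %d locations (%d total)\n",
              x$n_regions, x$towns_per_region, x$locations_per_town,
              nrow(x$locations)))
  invisible(x)
}

#' Generate geotagged events from a planted world
#'
#' Every user gets a uniformly drawn home town. Each of their events first
#' samples a movement regime — intra-town (a location of the home town),
#' intra-region (a location of another town in the home region), or
#' inter-region (a location in another region) — then a uniform location
#' within that stratum. The regime mixture is what plants the multi-modal
#' movement-distance distribution that the pipeline should resolve into
#' natural scales.
#'
#' @param world A [generate_world()] result.
#' @param n_users Number of users (default 500).
#' @param events_per_user Events per user (default 10).
#' @param p_intra_town,p_intra_region,p_inter_region Regime mixture; must sum
#'   to 1 (defaults 0.7 / 0.25 / 0.05).
#' @param seed Integer seed.
#' @return `data.frame` of events: `event_id`, `user_id`, `lat`, `lon`,
#'   `timestamp` (synthetic sequence), plus hidden column `location_id` (the
#'   generating location, before any nearest-seed reassignment).
#' @export
generate_events <- function(world, n_users = 500L, events_per_user = 10L,
                            p_intra_town = 0.7, p_intra_region = 0.25,
                            p_inter_region = 0.05, seed = 1L) {
  p <- c(p_intra_town, p_intra_region, p_inter_region)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("regime probabilities must be non-negative and sum to 1")
  }
  if (world$n_regions < 2 && p_inter_region > 0) {
    stop("inter-region movements need at least 2 regions")
  }
  if (world$towns_per_region < 2 && p_intra_region > 0) {
    stop("intra-region movements need at least 2 towns per region")
  }
  loc <- world$locations
  set.seed(derive_seed(seed, 2L))
  n_towns <- world$n_regions * world$towns_per_region
  home_town <- sample.int(n_towns, n_users, replace = TRUE)
  home_region <- (home_town - 1L) %/% world$towns_per_region + 1L
  ev <- vector("list", n_users)
  for (u in seq_len(n_users)) {
    regime <- sample.int(3L, events_per_user, replace = TRUE, prob = p)
    pick <- vapply(regime, function(rg) {
      pool <- switch(rg,
        which(loc$town == home_town[u]),
        which(loc$region == home_region[u] & loc$town != home_town[u]),
        which(loc$region != home_region[u])
      )
      pool[sample.int(length(pool), 1L)]
    }, integer(1))
    ev[[u]] <- data.frame(
      user_id = sprintf("U%04d", u),
      location_id = loc$location_id[pick],
      stringsAsFactors = FALSE
    )
  }
  events <- do.call(rbind, ev)
  li <- match(events$location_id, loc$location_id)
  events$lat <- loc$lat[li]
  events$lon <- loc$lon[li]
  events$event_id <- sprintf("E%06d", seq_len(nrow(events)))
  events$timestamp <- sprintf("2016-01-01T%02d:%02d:00Z",
                              (seq_len(nrow(events)) %/% 60) %% 24,
                              seq_len(nrow(events)) %% 60)
  rownames(events) <- NULL
  events[, c("event_id", "user_id", "lat", "lon", "timestamp", "location_id")]
}

#' Ground-truth partitions of a planted world
#'
#' @param world A [generate_world()] result.
#' @return List with `coarse` (region labels) and `fine` (town labels), both
#'   partitions over all locations. The fine partition refines the coarse one
#'   by construction.
#' @export
ground_truth_partitions <- function(world) {
  loc <- world$locations
  list(
    coarse = partition(loc$region, loc$location_id),
    fine = partition(loc$town, loc$location_id)
  )
}
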