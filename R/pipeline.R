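#' Detect the natural scales of a region's movement network
#'
#' Runs the full pipeline: assign events to their nearest seed location, build
#' the user co-occurrence graph, drop low-degree vertices, compute distance
#' percentile thresholds, then for each percentile restrict the graph, find
#' the best-of-N modularity partition and smooth it on the Voronoi
#' tessellation; finally compare all percentile partitions with the Rand
#' index, detect breakpoints in scale space, pick a prototypical percentile
#' per interval, tuple-smooth the prototypical partitions across scales and
#' extract geographic boundaries.
#'
#' @param events Events table (`data.frame` from [read_events()], or a CSV
#'   path).
#' @param locations Location seed table (`data.frame` from
#'   [read_locations()], or a CSV path).
#' @param config A [scales_config()].
#' @param verbose Print per-stage progress counts.
#' @return Object of class `"natural_scales"` with components `config`,
#'   `assignments`, `graph` (pruned movement graph), `thresholds`,
#'   `tessellation`, `partitions` (smoothed, one per percentile),
#'   `modularity` (per percentile), `scale_space`, `breakpoints`, `scales`
#'   (one entry per natural scale: `interval`, `prototype`,
#'   `distance_range_km`, `partition`, `multiscale_partition`), and
#'   `boundaries` (`data.frame` of segments with a `scale` column; scale 0 =
#'   multi-scale overlay rows are absent — each row belongs to one scale, the
#'   multiscale overlay is their union).
#' @export
natural_scales <- function(events, locations, config = scales_config(),
                           verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(events)) events <- read_events(events)
  if (is.character(locations)) locations <- read_locations(locations)
  stopifnot(inherits(config, "scales_config"))

  assignments <- assign_events_to_locations(events, locations)
  say("assigned %d events to %d seed locations", nrow(assignments),
      nrow(locations))
  graph <- build_cooccurrence_graph(assignments, locations)
  graph <- prune_low_degree(graph, config$min_vertex_degree)
  say("movement graph after degree-%d pruning: %d vertices, %d edges",
      config$min_vertex_degree, length(graph$vertices), nrow(graph$edges))
  if (length(graph$vertices) < 3) {
    stop("fewer than 3 locations survive pruning; not enough data")
  }
  thresholds <- percentile_thresholds(graph, config$n_percentiles,
                                      config$percentile_weighting)
  seeds <- locations[locations$location_id %in% graph$vertices, , drop = FALSE]
  tess <- build_tessellation(seeds)

  n <- config$n_percentiles
  partitions <- vector("list", n)
  modularity <- numeric(n)
  for (s in seq_len(n)) {
    gs <- percentile_graph(graph, s, thresholds)
    res <- detect_best_partition(gs, config$n_partition_runs,
                                 seed = config$random_seed, stage = s)
    partitions[[s]] <- smooth_partition(res$partition, tess,
                                        config$smoothing_max_sweeps)
    modularity[s] <- res$modularity
  }
  say("partitioned and smoothed %d percentile graphs", n)

  ss <- similarity_matrix(partitions)
  bp <- detect_breakpoints(ss, config$min_interval_size)
  say("breakpoints at %s (sigma = %.3f)",
      paste(bp$breaks, collapse = ", "), bp$sigma)

  scales <- lapply(seq_along(bp$intervals), function(j) {
    iv <- bp$intervals[[j]]
    proto <- prototypical_scale(ss, iv)
    list(
      interval = c(iv[["lo"]], iv[["hi"]]),
      prototype = proto,
      distance_range_km = c(
        if (iv[["lo"]] == 1) 0 else thresholds[iv[["lo"]] - 1],
        thresholds[iv[["hi"]]]
      ),
      partition = partitions[[proto]]
    )
  })
  multi <- smooth_multiscale(lapply(scales, `[[`, "partition"), tess,
                             config$smoothing_max_sweeps)
  for (j in seq_along(scales)) scales[[j]]$multiscale_partition <- multi[[j]]

  blist <- lapply(seq_along(scales), function(j) {
    b <- extract_boundaries(tess, scales[[j]]$multiscale_partition)
    if (nrow(b) > 0) b$scale <- j
    b
  })
  boundaries <- do.call(rbind, blist[vapply(blist, nrow, 0L) > 0])
  if (is.null(boundaries)) {
    boundaries <- cbind(extract_boundaries(tess, partitions[[1]])[0, ],
                        scale = integer(0))
  }

  structure(list(
    config = config, assignments = assignments, locations = locations,
    graph = graph, thresholds = thresholds, tessellation = tess,
    partitions = partitions, modularity = modularity,
    scale_space = ss, breakpoints = bp, scales = scales,
    boundaries = boundaries
  ), class = "natural_scales")
}

#' @export
print.natural_scales <- function(x, ...) {
  cat("Natural scales of the movement network\n")
  cat(sprintf("  %d locations, %d co-occurrence edges, %d percentile scales\n",
              length(x$graph$vertices), nrow(x$graph$edges),
              x$config$n_percentiles))
  cat(sprintf("  %d natural scale(s), breakpoints at {%s}, sigma = %.3f\n",
              length(x$scales), paste(x$breakpoints$breaks, collapse = ", "),
              x$breakpoints$sigma))
  for (j in seq_along(x$scales)) {
    sc <- x$scales[[j]]
    cat(sprintf("  scale %d: percentiles %d-%d, prototype %d, r in (%.1f, %.1f] km, %d communities\n",
                j, sc$interval[1], sc$interval[2], sc$prototype,
                sc$distance_range_km[1], sc$distance_range_km[2],
                length(unique(sc$partition))))
  }
  invisible(x)
}

#' @export
summary.natural_scales <- function(object, ...) {
  x <- object
  dis <- normalized_dissimilarity(x$scale_space)
  ivs <- x$breakpoints$intervals
  k <- length(ivs)
  # mean absolute dissimilarity per pair of intervals (the heatmap annotations)
  pairmean <- matrix(NA_real_, k, k)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      ia <- ivs[[a]][["lo"]]:ivs[[a]][["hi"]]
      ib <- ivs[[b]][["lo"]]:ivs[[b]][["hi"]]
      block <- 1 - x$scale_space$similarity[ia, ib, drop = FALSE]
      pairmean[a, b] <- if (a == b) {
        if (length(ia) == 1) 0 else mean(block[upper.tri(block)])
      } else mean(block)
    }
  }
  out <- list(
    n_scales = k,
    breaks = x$breakpoints$breaks,
    sigma = x$breakpoints$sigma,
    scales = data.frame(
      scale = seq_len(k),
      from_percentile = vapply(ivs, `[[`, 0L, "lo"),
      to_percentile = vapply(ivs, `[[`, 0L, "hi"),
      prototype = vapply(x$scales, `[[`, 0L, "prototype"),
      r_min_km = vapply(x$scales, function(s) s$distance_range_km[1], 0),
      r_max_km = vapply(x$scales, function(s) s$distance_range_km[2], 0),
      communities = vapply(x$scales, function(s)
        length(unique(s$partition)), 0L)
    ),
    interval_dissimilarity = pairmean,
    boundary_segments = nrow(x$boundaries)
  )
  class(out) <- "summary.natural_scales"
  out
}

#' @export
print.summary.natural_scales <- function(x, ...) {
  cat(sprintf("%d natural scale(s); breakpoints {%s}; sigma = %.3f\n",
              x$n_scales, paste(x$breaks, collapse = ", "), x$sigma))
  print(x$scales, row.names = FALSE)
  cat("mean absolute dissimilarity per interval pair:\n")
  print(round(x$interval_dissimilarity, 3))
  cat(x$boundary_segments, "boundary segment(s)\n")
  invisible(x)
}

#' Plot the normalised dissimilarity heatmap
#'
#' Percentiles on both axes; dark = similar, light = dissimilar. Dashed lines
#' mark detected breakpoints, dots the prototypical scales.
#'
#' @param x A [natural_scales()] fit.
#' @param ... Passed to [graphics::image()].
#' @export
plot.natural_scales <- function(x, ...) {
  d <- normalized_dissimilarity(x$scale_space)
  n <- nrow(d)
  graphics::image(1:n, 1:n, d, col = grDevices::hcl.colors(64, "inferno"),
                  xlab = "percentile scale", ylab = "percentile scale",
                  main = "normalised partition dissimilarity", ...)
  for (b in x$breakpoints$breaks) {
    graphics::abline(v = b - 0.5, h = b - 0.5, col = "dodgerblue", lty = 2)
  }
  protos <- vapply(x$scales, `[[`, 0L, "prototype")
  graphics::points(protos, protos, pch = 19, col = "green3")
  invisible(x)
}

#' Forced two-community division of the full graph
#'
#' Takes the best-of-N partition of the full (percentile-100) movement graph
#' and exhaustively merges its communities into the best two-community
#' partition — the classical single-scale bipartite analysis, useful to
#' compare the pipeline against two-community baselines. Boundaries of the
#' smoothed bipartition are included.
#'
#' @param fit A [natural_scales()] object, or a [movement_graph] plus
#'   `locations`.
#' @param locations Seed table; only needed when `fit` is a movement graph.
#' @param config A [scales_config()].
#' @return List: `result` (a `"partition_result"` with 2 communities),
#'   `smoothed` (its Voronoi-smoothed partition), `boundaries`.
#' @export
run_bipartition_report <- function(fit, locations = NULL,
                                   config = scales_config()) {
  if (inherits(fit, "natural_scales")) {
    graph <- fit$graph
    tess <- fit$tessellation
    config <- fit$config
  } else {
    graph <- fit
    if (is.null(locations)) stop("locations required with a movement graph")
    seeds <- locations[locations$location_id %in% graph$vertices, ,
                       drop = FALSE]
    tess <- build_tessellation(seeds)
  }
  best <- detect_best_partition(graph, config$n_partition_runs,
                                seed = config$random_seed, stage = 0L)
  res <- if (length(unique(best$partition)) >= 2) {
    exhaustive_bipartition(graph, best$partition)
  } else best
  smoothed <- smooth_partition(res$partition, tess,
                               config$smoothing_max_sweeps)
  list(result = res, smoothed = smoothed,
       boundaries = extract_boundaries(tess, smoothed))
}

#' Write pipeline artifacts to a directory
#'
#' Writes `results.json` (percentiles, thresholds, breakpoints, intervals,
#' prototypical scales, sigma), per-scale partition CSVs
#' (`partition_scale_<j>.csv` with columns `location_id,community`), the
#' similarity matrix CSV, and per-scale + multi-scale boundary GeoJSON.
#'
#' @param fit A [natural_scales()] object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(
    percentiles = fit$config$n_percentiles,
    thresholds_km = fit$thresholds,
    breakpoints = fit$breakpoints$breaks,
    sigma = fit$breakpoints$sigma,
    intervals = lapply(fit$breakpoints$intervals, function(iv)
      list(from = iv[["lo"]], to = iv[["hi"]])),
    prototypical_scales = vapply(fit$scales, `[[`, 0L, "prototype"),
    distance_ranges_km = lapply(fit$scales, function(s)
      list(from = s$distance_range_km[1], to = s$distance_range_km[2]))
  )
  jsonlite::write_json(res, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA)
  for (j in seq_along(fit$scales)) {
    p <- fit$scales[[j]]$multiscale_partition
    write.csv(data.frame(location_id = names(p), community = as.integer(p)),
              file.path(dir, sprintf("partition_scale_%d.csv", j)),
              row.names = FALSE)
  }
  write.csv(fit$scale_space$similarity,
            file.path(dir, "similarity_matrix.csv"), row.names = FALSE)
  for (j in seq_along(fit$scales)) {
    b <- fit$boundaries[fit$boundaries$scale == j, , drop = FALSE]
    write_boundaries_geojson(b, file.path(dir,
                                          sprintf("boundaries_scale_%d.geojson", j)))
  }
  write_boundaries_geojson(fit$boundaries,
                           file.path(dir, "boundaries_multiscale.geojson"))
  invisible(dir)
}
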