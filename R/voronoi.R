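#' Voronoi tessellation of the location seeds
#'
#' Computes the planar Voronoi diagram of the seed locations in lon-lat space,
#' clipped to a rectangle (default: bounding box of the seeds padded by 5% per
#' side). Two cells are adjacent iff they share a boundary edge of positive
#' length — cells meeting at a single point (co-circular seeds) are not
#' neighbours. Only topology feeds the smoothing stage, so working directly in
#' lon-lat (rather than a projection) is safe.
#'
#' @param locations `data.frame` with `location_id`, `lat`, `lon`; at least 3
#'   non-collinear seeds.
#' @param clip Optional clip rectangle `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param pad Padding fraction per side when `clip` is derived from the data.
#' @return Object of class `"tessellation"`: `seeds` (the input table),
#'   `clip`, `adjacency` (named list of neighbour id vectors), `edges`
#'   (`data.frame` `u,v,lon1,lat1,lon2,lat2` with one row per shared cell
#'   edge), `cells` (named list of polygon matrices with columns lon, lat).
#' @export
build_tessellation <- function(locations, clip = NULL, pad = 0.05) {
  if (nrow(locations) < 3) stop("need at least 3 seed locations")
  if (is.null(clip)) {
    rx <- range(locations$lon)
    ry <- range(locations$lat)
    dx <- max(diff(rx), 1e-6)
    dy <- max(diff(ry), 1e-6)
    clip <- c(rx[1] - pad * dx, rx[2] + pad * dx,
              ry[1] - pad * dy, ry[2] + pad * dy)
  }
  dd <- tryCatch(
    deldir::deldir(locations$lon, locations$lat, rw = clip,
                   suppressMsge = TRUE),
    error = function(e) stop("tessellation failed (collinear seeds?): ",
                             conditionMessage(e))
  )
  seg <- dd$dirsgs
  len <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2)
  tol <- 1e-9 * max(clip[2] - clip[1], clip[4] - clip[3])
  seg <- seg[len > tol, , drop = FALSE]
  ids <- locations$location_id
  edges <- data.frame(u = ids[seg$ind1], v = ids[seg$ind2],
                      lon1 = seg$x1, lat1 = seg$y1,
                      lon2 = seg$x2, lat2 = seg$y2,
                      stringsAsFactors = FALSE)
  swap <- edges$u > edges$v
  tmp <- edges$u[swap]; edges$u[swap] <- edges$v[swap]; edges$v[swap] <- tmp
  adjacency <- setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    adjacency[[id]] <- sort(unique(c(edges$v[edges$u == id],
                                     edges$u[edges$v == id])))
  }
  tl <- deldir::tile.list(dd)
  cells <- setNames(lapply(tl, function(t) {
    cbind(lon = t$x, lat = t$y)
  }), ids[vapply(tl, function(t) t$ptNum, integer(1))])
  structure(list(seeds = locations, clip = clip, adjacency = adjacency,
                 edges = edges, cells = cells),
            class = "tessellation")
}

#' @export
print.tessellation <- function(x, ...) {
  cat("Voronoi tessellation:", nrow(x$seeds), "cells,",
      nrow(x$edges), "shared edges\n")
  invisible(x)
}

# Generic synchronous majority smoothing over arbitrary cell values.
# A cell adopts a value held by a strict majority (> 1/2) of its closed
# neighbourhood (itself + adjacent cells) when that value differs from its
# own. Sweeps are synchronous (order-independent); stops at a fixed point,
# on a 2-cycle (the last state is returned), or after max_sweeps.
smooth_values <- function(values, adjacency, max_sweeps = 100L) {
  ids <- names(values)
  nbr <- lapply(ids, function(id) match(c(id, adjacency[[id]]), ids))
  prev <- NULL
  for (sweep in seq_len(max_sweeps)) {
    nxt <- values
    for (i in seq_along(ids)) {
      hood <- values[nbr[[i]]]
      tab <- table(hood)
      top <- names(tab)[which.max(tab)]
      if (top != values[[i]] && tab[[top]] * 2 > length(hood)) {
        nxt[[i]] <- top
      }
    }
    if (identical(nxt, values)) break        # fixed point
    if (!is.null(prev) && identical(nxt, prev)) { # 2-cycle guard
      values <- nxt
      break
    }
    prev <- values
    values <- nxt
  }
  values
}

#' Smooth a partition by closed-neighbourhood majority
#'
#' Removes residual spatial noise from a network-derived partition: in each
#' synchronous sweep a cell switches to a different community iff that
#' community holds a strict majority (more than half) of the cell's closed
#' neighbourhood — its Voronoi neighbours plus itself. Repeats until nothing
#' changes, a 2-cycle is detected, or `max_sweeps` is hit. A plurality short
#' of a majority never triggers a flip, and no new label can appear.
#'
#' @param p Partition whose domain contains all tessellation seeds.
#' @param tess A [build_tessellation()] result.
#' @param max_sweeps Sweep cap (default 100).
#' @return Smoothed partition over the tessellation seeds.
#' @export
smooth_partition <- function(p, tess, max_sweeps = 100L) {
  ids <- tess$seeds$location_id
  if (!all(ids %in% names(p))) stop("partition does not cover all seeds")
  vals <- as.character(p[ids])
  names(vals) <- ids
  out <- smooth_values(vals, tess$adjacency, max_sweeps)
  partition(out, ids)
}

#' Multi-scale tuple smoothing
#'
#' Applies the same strict-majority rule to whole tuples of per-scale labels:
#' each cell carries the vector of its community labels at every natural
#' scale, tuples are compared by exact equality, and a cell adopts a
#' different tuple iff that tuple holds a strict closed-neighbourhood
#' majority. This trades a little per-scale precision for boundaries that
#' align across scales.
#'
#' @param partitions List of partitions (ordered smallest to largest scale),
#'   all covering the tessellation seeds.
#' @param tess A [build_tessellation()] result.
#' @param max_sweeps Sweep cap (default 100).
#' @return List of smoothed partitions, the per-scale projections of the
#'   final tuples, in the input order.
#' @export
smooth_multiscale <- function(partitions, tess, max_sweeps = 100L) {
  ids <- tess$seeds$location_id
  for (p in partitions) {
    if (!all(ids %in% names(p))) stop("partition does not cover all seeds")
  }
  tuples <- vapply(ids, function(id) {
    paste(vapply(partitions, function(p) p[[id]], integer(1)), collapse = ",")
  }, character(1))
  out <- smooth_values(tuples, tess$adjacency, max_sweeps)
  labs <- do.call(rbind, strsplit(out, ",", fixed = TRUE))
  lapply(seq_along(partitions), function(k) {
    partition(as.integer(labs[, k]), ids)
  })
}

#' Boundary segments between communities
#'
#' Returns the shared Voronoi cell edges whose two seed locations belong to
#' different communities — the geographic boundaries implied by a partition.
#' Determined entirely by (adjacency, labels); independent of label numbering.
#'
#' @param tess A [build_tessellation()] result.
#' @param p Partition covering the tessellation seeds.
#' @return `data.frame` with columns `u`, `v`, `lon1`, `lat1`, `lon2`, `lat2`,
#'   one row per boundary segment.
#' @export
extract_boundaries <- function(tess, p) {
  ids <- tess$seeds$location_id
  if (!all(ids %in% names(p))) stop("partition does not cover all seeds")
  e <- tess$edges
  diff_lab <- p[e$u] != p[e$v]
  out <- e[diff_lab, , drop = FALSE]
  rownames(out) <- NULL
  out
}
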