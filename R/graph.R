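#' Movement graph container
#'
#' A movement graph has locations as vertices and an undirected edge for every
#' pair of locations sharing at least one user; the edge weight is the number
#' of distinct shared users and each edge carries its great-circle length in
#' km. Stored as a canonical edge list (`u < v` lexicographically) plus the
#' vertex set, which may include isolated vertices — percentile filtering keeps
#' the vertex set fixed so that all per-scale partitions share one domain.
#'
#' @param edges `data.frame` with columns `u`, `v`, `weight`, `distance_km`.
#' @param vertices Character vector of location ids (defaults to the ids
#'   appearing in `edges`).
#' @return Object of class `"movement_graph"`.
#' @export
movement_graph <- function(edges, vertices = NULL) {
  if (nrow(edges) > 0) {
    stopifnot(all(c("u", "v", "weight", "distance_km") %in% names(edges)))
    if (any(edges$u == edges$v)) stop("self-loops are not allowed")
    if (any(edges$weight < 1)) stop("edge weights must be >= 1")
    swap <- edges$u > edges$v
    tmp <- edges$u[swap]; edges$u[swap] <- edges$v[swap]; edges$v[swap] <- tmp
    if (anyDuplicated(paste(edges$u, edges$v, sep = "\r"))) {
      stop("duplicate edges")
    }
    edges <- edges[order(edges$u, edges$v), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(u = character(), v = character(),
                        weight = numeric(), distance_km = numeric())
  }
  vertices <- sort(unique(c(as.character(vertices), edges$u, edges$v)))
  structure(list(vertices = vertices, edges = edges), class = "movement_graph")
}

#' @export
print.movement_graph <- function(x, ...) {
  cat("Movement graph:", length(x$vertices), "locations,",
      nrow(x$edges), "co-occurrence edges\n")
  if (nrow(x$edges) > 0) {
    cat(sprintf("  distances %.3f - %.3f km, total movement weight %d\n",
                min(x$edges$distance_km), max(x$edges$distance_km),
                sum(x$edges$weight)))
  }
  invisible(x)
}

#' Build the user co-occurrence graph
#'
#' For every unordered pair of locations, the edge weight is the number of
#' distinct users with at least one event at both. Pairs sharing no user get
#' no edge; every location with at least one assigned event becomes a vertex.
#'
#' @param assignments `data.frame` with columns `user_id`, `location_id`
#'   (from [assign_events_to_locations()]).
#' @param locations Seed table with `location_id`, `lat`, `lon`; used for edge
#'   distances and to validate ids.
#' @return A [movement_graph].
#' @export
build_cooccurrence_graph <- function(assignments, locations) {
  unknown <- setdiff(assignments$location_id, locations$location_id)
  if (length(unknown) > 0) {
    stop("assignment references unknown location_id: ",
         paste(head(unknown, 3), collapse = ", "))
  }
  uv <- unique(assignments[, c("user_id", "location_id")])
  by_user <- split(uv$location_id, uv$user_id)
  pair_mats <- lapply(by_user, function(locs) {
    locs <- sort(unique(locs))
    if (length(locs) < 2) return(NULL)
    t(utils::combn(locs, 2))
  })
  pairs <- do.call(rbind, pair_mats)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    key <- paste(pairs[, 1], pairs[, 2], sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    u <- vapply(parts, `[[`, "", 1)
    v <- vapply(parts, `[[`, "", 2)
    w <- as.integer(tab)
    li <- match(u, locations$location_id)
    lj <- match(v, locations$location_id)
    d <- haversine_km(locations$lat[li], locations$lon[li],
                      locations$lat[lj], locations$lon[lj])
    edges <- data.frame(u = u, v = v, weight = w, distance_km = d,
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(u = character(), v = character(),
                        weight = numeric(), distance_km = numeric())
  }
  movement_graph(edges, vertices = unique(uv$location_id))
}

#' Drop low-degree vertices
#'
#' Removes vertices whose unweighted degree (number of neighbours) is below
#' `min_degree`, together with incident edges. Applied once — survivors whose
#' degree fell below the threshold through the removal are kept. Very
#' low-activity locations are prone to sampling noise and would pollute
#' community detection.
#'
#' @param graph A [movement_graph].
#' @param min_degree Minimum neighbour count to survive (default 5).
#' @return Pruned [movement_graph].
#' @export
prune_low_degree <- function(graph, min_degree = 5L) {
  stopifnot(min_degree >= 0)
  if (min_degree == 0 || length(graph$vertices) == 0) return(graph)
  deg <- setNames(integer(length(graph$vertices)), graph$vertices)
  tab <- table(c(graph$edges$u, graph$edges$v))
  deg[names(tab)] <- as.integer(tab)
  keep <- names(deg)[deg >= min_degree]
  e <- graph$edges
  e <- e[e$u %in% keep & e$v %in% keep, , drop = FALSE]
  movement_graph(e, vertices = keep)
}

#' Distance percentile thresholds
#'
#' Splits the edge distance distribution into `n` percentiles by the
#' nearest-rank rule: threshold `m[s]` is the `ceil(s * N / n)`-th smallest
#' distance, so `m[n]` is exactly the maximum. By default each distinct edge
#' counts once; with `weighting = "movements"` each edge is replicated by its
#' user-count weight so percentiles are over observed movements.
#'
#' @param graph A [movement_graph] with at least one edge.
#' @param n Number of percentiles (default 100).
#' @param weighting `"edges"` or `"movements"`.
#' @return Numeric vector `m` of length `n`, non-decreasing, in km.
#' @export
percentile_thresholds <- function(graph, n = 100L,
                                  weighting = c("edges", "movements")) {
  weighting <- match.arg(weighting)
  if (nrow(graph$edges) == 0) stop("graph has no edges")
  d <- graph$edges$distance_km
  if (weighting == "movements") d <- rep(d, times = graph$edges$weight)
  d <- sort(d)
  N <- length(d)
  d[pmax(1L, ceiling(seq_len(n) * N / n))]
}

#' Percentile graph
#'
#' The movement graph restricted to edges no longer than the `s`-th percentile
#' threshold. The vertex set is unchanged, so isolated vertices remain and all
#' percentile partitions share one domain.
#'
#' @param graph A [movement_graph].
#' @param s Percentile in `1..length(thresholds)`.
#' @param thresholds From [percentile_thresholds()].
#' @return A [movement_graph] with the filtered edge set.
#' @export
percentile_graph <- function(graph, s, thresholds) {
  if (s < 1 || s > length(thresholds)) stop("percentile out of range: ", s)
  e <- graph$edges[graph$edges$distance_km <= thresholds[s], , drop = FALSE]
  movement_graph(e, vertices = graph$vertices)
}

# igraph view of a movement_graph (weights on E(g)$weight)
as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(graph$vertices),
                            name = graph$vertices)
  if (nrow(graph$edges) > 0) {
    g <- igraph::add_edges(g, rbind(graph$edges$u, graph$edges$v),
                           weight = graph$edges$weight)
  }
  g
}
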