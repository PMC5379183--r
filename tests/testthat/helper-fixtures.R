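# Shared fixtures and independent oracles. Oracles are deliberately naive
# (pair enumeration, mask enumeration, external implementations) so they never
# share code paths with the package internals they check.

# locations laid out on an nx x ny grid, spacing in degrees
grid_locations <- function(nx, ny, spacing = 0.1, origin = c(50, 8)) {
  g <- expand.grid(col = seq_len(nx) - 1, row = seq_len(ny) - 1)
  data.frame(
    location_id = sprintf("G%02d%02d", g$row, g$col),
    lat = origin[1] + g$row * spacing,
    lon = origin[2] + g$col * spacing,
    stringsAsFactors = FALSE
  )
}

random_partition <- function(ids, k) {
  partition(sample.int(k, length(ids), replace = TRUE), ids)
}

# O(n^2) Rand index by explicit pair enumeration via pair_agreement
rand_oracle <- function(p, q) {
  ids <- names(p)
  n <- length(ids)
  agree <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (pair_agreement(p, ids[i], ids[j]) ==
          pair_agreement(q, ids[i], ids[j])) {
        agree <- agree + 1L
      }
    }
  }
  agree / (n * (n - 1) / 2)
}

# random weighted movement graph over n vertices; Erdos-Renyi-ish with a
# planted blocky bias so Louvain finds a handful of communities
random_movement_graph <- function(n, p = 0.25, blocks = 3) {
  ids <- sprintf("V%02d", seq_len(n))
  blk <- rep(seq_len(blocks), length.out = n)
  rows <- list()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      pe <- if (blk[i] == blk[j]) min(1, 3 * p) else p / 3
      if (stats::runif(1) < pe) {
        rows[[length(rows) + 1L]] <- data.frame(
          u = ids[i], v = ids[j],
          weight = sample.int(4, 1),
          distance_km = stats::runif(1, 1, 100)
        )
      }
    }
  }
  if (length(rows) == 0) return(movement_graph(data.frame(
    u = character(), v = character(), weight = numeric(),
    distance_km = numeric()), vertices = ids))
  movement_graph(do.call(rbind, rows), vertices = ids)
}

# graph of two disconnected k-cliques, unit weights
two_cliques_graph <- function(k) {
  mk <- function(prefix) {
    ids <- paste0(prefix, seq_len(k))
    pairs <- t(combn(ids, 2))
    data.frame(u = pairs[, 1], v = pairs[, 2], weight = 1,
               distance_km = 1, stringsAsFactors = FALSE)
  }
  movement_graph(rbind(mk("a"), mk("b")))
}

# brute-force best merge of a partition's communities into two groups,
# scored with igraph's modularity (independent of the package's formula)
bipartition_oracle <- function(graph, p) {
  p <- canonical_partition(p[graph$vertices])
  k <- length(unique(p))
  g <- igraph::graph_from_data_frame(graph$edges[, c("u", "v")],
                                     directed = FALSE,
                                     vertices = graph$vertices)
  w <- graph$edges$weight
  best <- -Inf
  best_memb <- NULL
  for (mask in 1:(2^(k - 1) - 1)) {
    inB <- c(FALSE, as.logical(bitwAnd(bitwShiftR(mask, 0:(k - 2)), 1L)))
    memb <- ifelse(inB[p[igraph::V(g)$name] + 1L], 2L, 1L)
    q <- igraph::modularity(g, memb, weights = w)
    if (q > best + 1e-12) {
      best <- q
      best_memb <- memb
    }
  }
  list(modularity = best, membership = best_memb)
}

# block similarity matrix: within-block entries `within`, across `across`,
# unit diagonal; `sizes` gives consecutive block lengths
block_similarity <- function(sizes, within = 0.9, across = 0.1) {
  n <- sum(sizes)
  blk <- rep(seq_along(sizes), times = sizes)
  m <- matrix(across, n, n)
  for (b in seq_along(sizes)) m[blk == b, blk == b] <- within
  diag(m) <- 1
  m
}

# tiny two-level world + events used by several pipeline tests (kept small
# so unit tests stay fast; acceptance uses the full study conditions)
small_world_fixture <- function(seed = 1) {
  w <- generate_world(n_regions = 2, towns_per_region = 2,
                      locations_per_town = 8, seed = seed)
  ev <- generate_events(w, n_users = 150, events_per_user = 8, seed = seed)
  list(world = w, events = ev)
}

# even-odd winding point-in-polygon (poly: matrix with columns lon, lat)
point_in_polygon <- function(pt, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((y[i] > pt[2]) != (y[j] > pt[2]) &&
        pt[1] < (x[j] - x[i]) * (pt[2] - y[i]) / (y[j] - y[i]) + x[i]) {
      inside <- !inside
    }
    j <- i
  }
  inside
}
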