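#' Weighted Newman-Girvan modularity
#'
#' \deqn{Q = \sum_c \left( \frac{e_c}{m} - \left(\frac{d_c}{2m}\right)^2 \right)}
#' where, over edge weights, \eqn{m} is the total, \eqn{e_c} the weight inside
#' community \eqn{c} and \eqn{d_c} the summed degree of its vertices. Measures
#' how much more edge weight falls inside communities than expected under a
#' degree-preserving random rewiring. An edgeless graph has modularity 0 by
#' convention.
#'
#' @param graph A [movement_graph].
#' @param p Partition covering every vertex of `graph`.
#' @return Modularity in \[-0.5, 1\].
#' @export
graph_modularity <- function(graph, p) {
  missing <- setdiff(graph$vertices, names(p))
  if (length(missing) > 0) {
    stop("partition does not cover vertex: ", missing[1])
  }
  e <- graph$edges
  if (nrow(e) == 0) return(0)
  m <- sum(e$weight)
  cu <- p[e$u]
  cv <- p[e$v]
  e_in <- sum(e$weight[cu == cv])
  # weighted degree per community
  deg <- tapply(c(e$weight, e$weight), c(cu, cv), sum)
  e_in / m - sum((deg / (2 * m))^2)
}

#' Best-of-N modularity partition
#'
#' Runs the Louvain heuristic (igraph's implementation) `n_runs` times with
#' deterministic run-derived seeds and keeps the run with the highest
#' modularity (ties: first run). Isolated vertices end up as singleton
#' communities. The restarts both improve partition quality and stabilise
#' partitions across neighbouring scales.
#'
#' @param graph A [movement_graph].
#' @param n_runs Number of restarts (default 100).
#' @param seed Master seed for the run sequence.
#' @param stage Integer mixed into the per-run seeds; callers processing many
#'   graphs (one per percentile) pass the percentile here so runs differ
#'   across scales but stay reproducible.
#' @return List of class `"partition_result"`: `partition` (named integer
#'   vector), `modularity`, `n_runs`, `seed`.
#' @export
detect_best_partition <- function(graph, n_runs = 100L, seed = 1L,
                                  stage = 0L) {
  stopifnot(n_runs >= 1)
  if (length(graph$vertices) == 0) {
    return(structure(list(partition = partition(integer(0), character(0)),
                          modularity = 0, n_runs = n_runs, seed = seed),
                     class = "partition_result"))
  }
  if (nrow(graph$edges) == 0) {
    p <- partition(seq_along(graph$vertices) - 1L, graph$vertices)
    return(structure(list(partition = p, modularity = 0,
                          n_runs = n_runs, seed = seed),
                     class = "partition_result"))
  }
  g <- as_igraph(graph)
  best <- NULL
  for (run in seq_len(n_runs)) {
    set.seed(derive_seed(seed, stage, run))
    cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
    memb <- igraph::membership(cl)
    p <- partition(as.integer(memb), igraph::V(g)$name)
    q <- graph_modularity(graph, p)
    if (is.null(best) || q > best$modularity + 1e-12) {
      best <- list(partition = canonical_partition(p), modularity = q)
    }
  }
  structure(list(partition = best$partition, modularity = best$modularity,
                 n_runs = n_runs, seed = seed),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  k <- length(unique(x$partition))
  cat(sprintf("Partition: %d locations in %d communities, modularity %.4f (%d runs)\n",
              length(x$partition), k, x$modularity, x$n_runs))
  invisible(x)
}

#' Best merge of a partition into two communities
#'
#' Exhaustively evaluates every way of merging the k communities of `p` into
#' two non-empty groups (2^(k-1) - 1 candidates) and returns the merge with
#' the highest modularity; ties break towards the first candidate in the
#' canonical enumeration (binary masks over communities 2..k in ascending
#' order). Used to force a bipartite division of a territory for comparison
#' with classical two-community analyses.
#'
#' @param graph A [movement_graph].
#' @param p Partition of `graph`'s vertices with 2 <= k <= 25 communities.
#' @return A `"partition_result"` whose partition has exactly 2 communities.
#' @export
exhaustive_bipartition <- function(graph, p) {
  p <- canonical_partition(p[graph$vertices])
  k <- length(unique(p))
  if (k < 2) stop("partition must have at least 2 communities")
  if (k > 25) stop("too many communities to enumerate (k = ", k, " > 25)")
  # community-level aggregates: within/between weights and degrees
  e <- graph$edges
  m <- sum(e$weight)
  if (m == 0) stop("graph has no edges")
  cu <- p[e$u]
  cv <- p[e$v]
  W <- matrix(0, k, k)
  for (i in seq_len(nrow(e))) {
    a <- cu[i] + 1L; b <- cv[i] + 1L
    W[a, b] <- W[a, b] + e$weight[i]
    if (a != b) W[b, a] <- W[b, a] + e$weight[i]
  }
  deg <- rowSums(W) + diag(W) # internal weight counts twice in degree
  best_q <- -Inf
  best_mask <- NULL
  # community 1 fixed in group A; masks enumerate membership of 2..k
  for (mask in 1:(2^(k - 1) - 1)) {
    inB <- c(FALSE, as.logical(bitwAnd(bitwShiftR(mask, 0:(k - 2)), 1L)))
    q <- 0
    for (grp in list(which(!inB), which(inB))) {
      e_in <- sum(W[grp, grp, drop = FALSE][upper.tri(W[grp, grp, drop = FALSE])]) +
        sum(diag(W)[grp])
      q <- q + e_in / m - (sum(deg[grp]) / (2 * m))^2
    }
    if (q > best_q + 1e-12) {
      best_q <- q
      best_mask <- inB
    }
  }
  merged <- ifelse(best_mask[p + 1L], 1L, 0L)
  names(merged) <- names(p)
  structure(list(partition = canonical_partition(merged),
                 modularity = best_q, n_runs = 1L, seed = NA_integer_),
            class = "partition_result")
}
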