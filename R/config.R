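#' Pipeline configuration
#'
#' Bundles the tunable parameters of the natural-scales pipeline. Defaults
#' follow the reference protocol: 100 distance percentiles, a one-shot degree-5
#' vertex filter, 100 community-detection runs per percentile graph, a minimum
#' breakpoint interval of 5 percentiles, and distance percentiles taken over
#' distinct edges.
#'
#' @param n_percentiles Number of distance percentiles / scales (default 100).
#' @param min_vertex_degree Vertices with unweighted degree below this are
#'   dropped once, before percentile graphs are built (default 5).
#' @param n_partition_runs Community-detection restarts per percentile graph;
#'   the best-modularity run wins (default 100).
#' @param min_interval_size Minimum breakpoint interval length, in percentiles
#'   (default 5); prevents noisy outlying scales from being isolated.
#' @param random_seed Integer master seed; all run-level seeds derive from it.
#' @param percentile_weighting `"edges"` (default) ranks each distinct edge
#'   once when computing distance percentiles; `"movements"` replicates each
#'   edge by its user-count weight, so percentiles are over observed movements.
#' @param smoothing_max_sweeps Cap on majority-smoothing sweeps (default 100).
#' @return Object of class `"scales_config"` (a validated list).
#' @export
scales_config <- function(n_percentiles = 100L,
                          min_vertex_degree = 5L,
                          n_partition_runs = 100L,
                          min_interval_size = 5L,
                          random_seed = 1L,
                          percentile_weighting = c("edges", "movements"),
                          smoothing_max_sweeps = 100L) {
  percentile_weighting <- match.arg(percentile_weighting)
  cfg <- list(
    n_percentiles = as.integer(n_percentiles),
    min_vertex_degree = as.integer(min_vertex_degree),
    n_partition_runs = as.integer(n_partition_runs),
    min_interval_size = as.integer(min_interval_size),
    random_seed = as.integer(random_seed),
    percentile_weighting = percentile_weighting,
    smoothing_max_sweeps = as.integer(smoothing_max_sweeps)
  )
  stopifnot(
    cfg$n_percentiles >= 1, cfg$n_partition_runs >= 1,
    cfg$min_interval_size >= 1, cfg$min_vertex_degree >= 0,
    cfg$smoothing_max_sweeps >= 1
  )
  structure(cfg, class = "scales_config")
}

# Deterministic per-(stage, run) seed derived from the master seed, so the
# whole pipeline is reproducible and individual stages can be re-run in
# isolation. Kept below 2^31 - 1.
derive_seed <- function(seed, stage, run = 0L) {
  (as.double(seed) * 48271 + as.double(stage) * 10007 + as.double(run)) %%
    2147483647
}
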