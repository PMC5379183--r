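#' Scale space: per-percentile partitions and their similarity matrix
#'
#' Collects the (smoothed) partition at every distance percentile and the
#' matrix of pairwise Rand similarities \eqn{\delta(P_s, P_{s'})}. The matrix
#' is symmetric with unit diagonal; phase structure in it is what breakpoint
#' detection exploits.
#'
#' @param partitions List of partitions, one per percentile in order, all
#'   sharing one location domain.
#' @return Object of class `"scale_space"`: `partitions`, `similarity`
#'   (n x n matrix), `n_percentiles`.
#' @export
similarity_matrix <- function(partitions) {
  n <- length(partitions)
  dom <- names(partitions[[1]])
  for (p in partitions) {
    if (!setequal(names(p), dom)) stop("partitions must share one domain")
  }
  sim <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sim[i, j] <- sim[j, i] <- rand_similarity(partitions[[i]], partitions[[j]])
    }
  }
  structure(list(partitions = partitions, similarity = sim, n_percentiles = n),
            class = "scale_space")
}

#' @export
print.scale_space <- function(x, ...) {
  cat("Scale space:", x$n_percentiles, "percentile partitions over",
      length(x$partitions[[1]]), "locations\n")
  off <- x$similarity[upper.tri(x$similarity)]
  cat(sprintf("  pairwise Rand similarity: min %.3f, median %.3f, max %.3f\n",
              min(off), stats::median(off), max(off)))
  invisible(x)
}

#' Normalised dissimilarity matrix
#'
#' `1 - similarity`, rescaled so its largest entry is 1: 0 is a perfect
#' match, 1 the largest dissimilarity observed in this region. A monotone
#' transform — entry ordering is preserved — used for heatmap display.
#'
#' @param ss A [similarity_matrix()] result (or a plain similarity matrix).
#' @return Matrix with entries in \[0, 1\].
#' @export
normalized_dissimilarity <- function(ss) {
  sim <- if (inherits(ss, "scale_space")) ss$similarity else ss
  d <- 1 - sim
  mx <- max(d)
  if (mx == 0) {
    warning("all partitions identical; dissimilarity is degenerate")
    return(d)
  }
  d / mx
}

# intervals implied by interior breakpoints over percentiles 1..n:
# breaks b partition 1..n into [b_{j-1}, b_j - 1] with sentinels 1 and n+1
breakpoint_intervals <- function(breaks, n) {
  bounds <- c(1L, sort(as.integer(breaks)), n + 1L)
  lapply(seq_len(length(bounds) - 1L), function(j) {
    c(lo = bounds[j], hi = bounds[j + 1L] - 1L)
  })
}

#' Interval separation of a breakpoint configuration
#'
#' The objective of breakpoint detection: the ratio between the size-weighted
#' mean within-interval similarity and the worst (largest) similarity between
#' the consecutive partitions straddling a breakpoint,
#' \deqn{\sigma(B) = \frac{\sum_j |I_j| \, \overline{\delta}(I_j) / \sum_j |I_j|}
#'                      {\max_{b \in B} \delta(P_{b-1}, P_b)}.}
#' Within-interval similarity averages over all unordered percentile pairs in
#' the interval; a singleton interval contributes similarity 1. The higher
#' \eqn{\sigma}, the more coherent the intervals and the sharper the
#' transitions. Returns `Inf` when some straddling similarity is 0.
#'
#' @param ss A [similarity_matrix()] result or plain similarity matrix.
#' @param breaks Non-empty set of interior breakpoints, each in `2..n`.
#' @return `sigma`, a non-negative scalar (possibly `Inf`).
#' @export
interval_separation <- function(ss, breaks) {
  sim <- if (inherits(ss, "scale_space")) ss$similarity else ss
  n <- nrow(sim)
  breaks <- sort(unique(as.integer(breaks)))
  if (length(breaks) == 0) stop("sigma is undefined without breakpoints")
  if (any(breaks < 2 | breaks > n)) stop("breakpoints must lie in 2..n")
  ivs <- breakpoint_intervals(breaks, n)
  num <- 0
  wsum <- 0
  for (iv in ivs) {
    size <- iv[["hi"]] - iv[["lo"]] + 1L
    within <- if (size == 1) 1 else {
      block <- sim[iv[["lo"]]:iv[["hi"]], iv[["lo"]]:iv[["hi"]]]
      mean(block[upper.tri(block)])
    }
    num <- num + size * within
    wsum <- wsum + size
  }
  den <- max(sim[cbind(breaks - 1L, breaks)])
  if (den == 0) return(Inf)
  (num / wsum) / den
}

#' Greedy breakpoint detection
#'
#' Finds the phase transitions in scale space: starting from no breakpoints,
#' each iteration evaluates every feasible additional breakpoint (feasible =
#' every resulting interval has at least `min_interval_size` percentiles) and
#' adds the one maximising the interval separation \eqn{\sigma}; ties break
#' towards the smaller percentile. The first breakpoint is always placed
#' (\eqn{\sigma} is undefined without one); afterwards the algorithm stops as
#' soon as no addition strictly increases \eqn{\sigma}.
#'
#' @param ss A [similarity_matrix()] result or plain similarity matrix.
#' @param min_interval_size Minimum interval length in percentiles (default
#'   5); guards against isolating noisy outlying scales.
#' @return List of class `"breakpoint_set"`: `breaks` (sorted interior
#'   breakpoints), `sigma`, `intervals` (list of `c(lo, hi)`), and `trace`
#'   (`data.frame` of the sigma value after each accepted addition).
#' @export
detect_breakpoints <- function(ss, min_interval_size = 5L) {
  sim <- if (inherits(ss, "scale_space")) ss$similarity else ss
  n <- nrow(sim)
  if (n < 2 * min_interval_size) {
    stop("need at least 2 * min_interval_size percentiles")
  }
  feasible <- function(breaks, cand) {
    bounds <- c(1L, sort(c(breaks, cand)), n + 1L)
    all(diff(bounds) >= min_interval_size)
  }
  breaks <- integer(0)
  sigma <- -Inf
  trace <- list()
  repeat {
    cands <- setdiff(2:n, breaks)
    cands <- cands[vapply(cands, function(b) feasible(breaks, b), logical(1))]
    if (length(cands) == 0) {
      if (length(breaks) == 0) stop("no feasible breakpoint position")
      break
    }
    sig <- vapply(cands, function(b) interval_separation(sim, c(breaks, b)),
                  numeric(1))
    best <- which.max(sig) # ties: first = smallest percentile (cands sorted)
    if (length(breaks) > 0 && sig[best] <= sigma) break
    breaks <- sort(c(breaks, cands[best]))
    sigma <- sig[best]
    trace[[length(trace) + 1L]] <- data.frame(step = length(breaks),
                                              added = cands[best],
                                              sigma = sigma)
  }
  structure(list(breaks = breaks, sigma = sigma,
                 intervals = breakpoint_intervals(breaks, n),
                 trace = do.call(rbind, trace)),
            class = "breakpoint_set")
}

#' @export
print.breakpoint_set <- function(x, ...) {
  cat("Breakpoints at percentiles:", paste(x$breaks, collapse = ", "),
      sprintf("(sigma = %.3f)\n", x$sigma))
  for (iv in x$intervals) {
    cat(sprintf("  interval %d-%d\n", iv["lo"], iv["hi"]))
  }
  invisible(x)
}

#' Prototypical scale of an interval
#'
#' The percentile inside the interval whose partition is most similar to all
#' the interval's other partitions (largest within-interval similarity sum);
#' ties break towards the smaller percentile. Its partition is used as the
#' visual representative of the natural scale.
#'
#' @param ss A [similarity_matrix()] result or plain similarity matrix.
#' @param interval `c(lo, hi)` percentile range.
#' @return The prototypical percentile (integer).
#' @export
prototypical_scale <- function(ss, interval) {
  sim <- if (inherits(ss, "scale_space")) ss$similarity else ss
  lo <- as.integer(interval[[1]])
  hi <- as.integer(interval[[2]])
  idx <- lo:hi
  if (length(idx) == 1) return(lo)
  block <- sim[idx, idx, drop = FALSE]
  score <- rowSums(block) - diag(block)
  idx[which.max(score)]
}

#' Which natural scales does each user contribute to?
#'
#' A user contributes to a natural scale if at least one of their movements —
#' a pair of distinct visited locations — has a length inside that scale's
#' absolute distance range. Ranges are half-open `(lower, upper]`, the first
#' closed below at 0, so each movement maps to exactly one scale. Activity is
#' the number of distinct locations a user visited.
#'
#' @param assignments `data.frame` with `user_id`, `location_id`.
#' @param locations Seed table (`location_id`, `lat`, `lon`).
#' @param scales List of natural scales as returned in
#'   [natural_scales()]`$scales` (each with `distance_range_km = c(lo, hi)`).
#' @return List with `users` (`data.frame`: `user_id`, `scale_set` such as
#'   `"12"`, `activity`) and `summary` (per scale-set: user count, mean
#'   activity, activity normalised by the largest set mean).
#' @export
user_scale_contributions <- function(assignments, locations, scales) {
  uv <- unique(assignments[, c("user_id", "location_id")])
  li <- match(uv$location_id, locations$location_id)
  uv$lat <- locations$lat[li]
  uv$lon <- locations$lon[li]
  lo_bounds <- vapply(scales, function(s) s$distance_range_km[[1]], numeric(1))
  hi_bounds <- vapply(scales, function(s) s$distance_range_km[[2]], numeric(1))
  per_user <- lapply(split(uv, uv$user_id), function(d) {
    k <- nrow(d)
    if (k < 2) {
      return(list(set = "", activity = k))
    }
    ij <- utils::combn(k, 2)
    dist <- haversine_km(d$lat[ij[1, ]], d$lon[ij[1, ]],
                         d$lat[ij[2, ]], d$lon[ij[2, ]])
    contributed <- which(vapply(seq_along(scales), function(s) {
      lo <- if (s == 1) -Inf else lo_bounds[s]
      any(dist > lo & dist <= hi_bounds[s])
    }, logical(1)))
    list(set = paste(contributed, collapse = ""), activity = k)
  })
  users <- data.frame(
    user_id = names(per_user),
    scale_set = vapply(per_user, `[[`, "", "set"),
    activity = vapply(per_user, function(x) as.numeric(x$activity), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  agg <- split(users$activity, users$scale_set)
  summary <- data.frame(
    scale_set = names(agg),
    n_users = vapply(agg, length, integer(1)),
    mean_activity = vapply(agg, mean, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  summary$relative_activity <- summary$mean_activity / max(summary$mean_activity)
  list(users = users, summary = summary)
}
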