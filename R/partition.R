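#' Partitions of a location set
#'
#' A partition assigns every location to exactly one community. Throughout the
#' package a partition is a named integer vector: names are location ids,
#' values are community labels. Labels are arbitrary — every downstream
#' computation is invariant under relabelling — but [canonical_partition()]
#' renumbers them 0..k-1 in order of first appearance for stable serialisation.
#'
#' @param labels Vector of community labels (coercible to integer or factor).
#' @param ids Character vector of location ids, same length as `labels`.
#' @return Named integer vector with class unchanged (plain vector).
#' @seealso [rand_similarity()], [canonical_partition()]
#' @export
partition <- function(labels, ids = names(labels)) {
  if (is.null(ids)) stop("partition labels must be named by location id")
  if (anyDuplicated(ids)) stop("duplicate location ids in partition")
  p <- as.integer(as.factor(labels)) - 1L
  names(p) <- as.character(ids)
  p
}

#' Renumber community labels to 0..k-1
#'
#' @param p Partition (named integer vector).
#' @return Partition with labels renumbered contiguously in order of first
#'   appearance.
#' @export
canonical_partition <- function(p) {
  u <- unique(p)
  q <- match(p, u) - 1L
  names(q) <- names(p)
  q
}

#' Co-membership indicator for a pair of locations
#'
#' Returns 1 if locations `i` and `j` belong to the same community of `p`,
#' 0 otherwise.
#'
#' @param p Partition.
#' @param i,j Location ids.
#' @return 0 or 1.
#' @export
pair_agreement <- function(p, i, j) {
  if (!(i %in% names(p)) || !(j %in% names(p))) {
    stop("location not in partition domain: ", if (i %in% names(p)) j else i)
  }
  as.integer(p[[i]] == p[[j]])
}

#' Rand similarity between two partitions of the same location set
#'
#' The fraction of unordered location pairs classified concordantly by the two
#' partitions — both together or both apart. Computed from the contingency
#' table of the two labelings, which is algebraically identical to enumerating
#' all pairs:
#' \deqn{\delta = 1 - (S_1 + S_2 - 2 S_{12}) / \binom{n}{2}}
#' where \eqn{S_1, S_2} count within-community pairs of each partition and
#' \eqn{S_{12}} pairs within communities of both.
#'
#' @param p,q Partitions over identical domains (same names, any order).
#' @return Similarity in \[0, 1\]; 1 means identical grouping.
#' @export
rand_similarity <- function(p, q) {
  if (length(p) != length(q) || !setequal(names(p), names(q))) {
    stop("partitions must share the same location domain")
  }
  n <- length(p)
  if (n < 2) stop("Rand similarity needs at least 2 locations")
  q <- q[names(p)]
  tab <- table(p, q)
  pairs2 <- function(x) sum(x * (x - 1) / 2)
  s12 <- pairs2(as.vector(tab))
  s1 <- pairs2(rowSums(tab))
  s2 <- pairs2(colSums(tab))
  total <- n * (n - 1) / 2
  1 - (s1 + s2 - 2 * s12) / total
}
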