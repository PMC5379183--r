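test_that("pair agreement is the symmetric co-membership indicator", {
  p <- partition(c(a = 1, b = 1, c = 2))
  expect_equal(pair_agreement(p, "a", "b"), 1)
  expect_equal(pair_agreement(p, "a", "c"), 0)
  set.seed(3)
  q <- random_partition(letters[1:8], 3)
  for (i in letters[1:8]) {
    for (j in letters[1:8]) {
      expect_equal(pair_agreement(q, i, j), pair_agreement(q, j, i))
    }
  }
  expect_error(pair_agreement(p, "a", "z"), "not in partition domain")
})

test_that("Rand similarity reproduces the worked three-location example", {
  p <- partition(c(a = 1, b = 1, c = 2))
  q <- partition(c(a = 1, b = 2, c = 3))
  # of the 3 pairs only (a,b) is classified differently -> 2/3
  expect_equal(rand_similarity(p, q), 2 / 3)
  expect_equal(rand_similarity(p, p), 1)
  expect_error(rand_similarity(p, q[1:2]), "domain")
  expect_error(rand_similarity(partition(c(a = 1)), partition(c(a = 1))),
               "at least 2")
})

test_that("Rand similarity equals pair enumeration and ignores labels", {
  set.seed(29)
  ids <- sprintf("n%02d", 1:40)
  for (rep in 1:10) {
    p <- random_partition(ids, sample(2:6, 1))
    q <- random_partition(ids, sample(2:6, 1))
    d <- rand_similarity(p, q)
    expect_equal(d, rand_oracle(p, q))
    expect_equal(d, rand_similarity(q, p))
    # label permutation invariance
    perm <- partition(sample(100, 6)[p + 1], names(p))
    expect_equal(rand_similarity(perm, q), d)
  }
})

test_that("similarity matrices are symmetric with unit diagonal", {
  set.seed(37)
  ids <- letters[1:10]
  ps <- replicate(6, random_partition(ids, 3), simplify = FALSE)
  ss <- similarity_matrix(ps)
  expect_equal(ss$similarity, t(ss$similarity))
  expect_equal(diag(ss$similarity), rep(1, 6))
  # identical partitions give the all-ones matrix
  same <- similarity_matrix(replicate(4, ps[[1]], simplify = FALSE))
  expect_equal(same$similarity, matrix(1, 4, 4))
  # alternating two partitions gives the checkerboard of their delta
  d <- rand_similarity(ps[[1]], ps[[2]])
  alt <- similarity_matrix(ps[c(1, 2, 1, 2)])
  expect_equal(alt$similarity[1, 2], d)
  expect_equal(alt$similarity[1, 3], 1)
  expect_equal(alt$similarity[2, 4], 1)
})

test_that("normalised dissimilarity anchors the extremes and preserves order", {
  sim <- block_similarity(c(3, 3), within = 0.8, across = 0.4)
  nd <- normalized_dissimilarity(sim)
  expect_equal(max(nd), 1)        # the 0.4 entries map to 1
  expect_equal(diag(nd), rep(0, 6))
  expect_equal(order(as.vector(1 - sim)), order(as.vector(nd)))
  expect_warning(out <- normalized_dissimilarity(matrix(1, 3, 3)),
                 "degenerate")
  expect_equal(out, matrix(0, 3, 3))
})

test_that("interval separation matches hand computation on block matrices", {
  sim <- block_similarity(c(10, 10), within = 0.9, across = 0.1)
  expect_equal(interval_separation(sim, 11), 9)
  # splitting inside a block puts a 0.9 pair across the cut: sigma drops
  expect_lt(interval_separation(sim, 6), 9)
  # identical partitions: all delta 1 -> sigma 1 for any breakpoint set
  ones <- matrix(1, 20, 20)
  expect_equal(interval_separation(ones, 11), 1)
  expect_equal(interval_separation(ones, c(6, 11, 16)), 1)
  # zero similarity across the cut -> infinite separation
  hard <- block_similarity(c(10, 10), within = 0.9, across = 0)
  expect_equal(interval_separation(hard, 11), Inf)
  expect_error(interval_separation(sim, integer(0)), "undefined")
  expect_error(interval_separation(sim, 1), "2..n")
})

test_that("greedy breakpoint search recovers planted blocks", {
  sim2 <- block_similarity(c(10, 10), within = 0.9, across = 0.1)
  bp <- detect_breakpoints(sim2, min_interval_size = 5)
  expect_equal(bp$breaks, 11L)
  expect_equal(bp$sigma, 9)
  expect_equal(length(bp$intervals), 2)

  sim3 <- block_similarity(c(30, 30, 40), within = 0.9, across = 0.1)
  bp3 <- detect_breakpoints(sim3, min_interval_size = 5)
  expect_equal(bp3$breaks, c(31L, 61L))
  # greedy trace: two accepted additions, sigma rising
  expect_equal(nrow(bp3$trace), 2)
  expect_lt(bp3$trace$sigma[1], bp3$trace$sigma[2])
})

test_that("exhaustive single-breakpoint scan confirms the greedy optimum", {
  sim <- block_similarity(c(10, 10), within = 0.9, across = 0.1)
  sigmas <- vapply(6:16, function(b) interval_separation(sim, b), numeric(1))
  expect_equal((6:16)[which.max(sigmas)], 11)
  # moving the breakpoint off the planted cut strictly lowers sigma
  expect_true(all(sigmas[(6:16) != 11] < max(sigmas)))
})

test_that("minimum interval size protects terminal noise scales", {
  # last 3 percentiles are an alien block; isolating them is infeasible
  sim <- block_similarity(c(47, 50, 3), within = 0.9, across = 0.1)
  bp <- detect_breakpoints(sim, min_interval_size = 5)
  sizes <- vapply(bp$intervals, function(iv) iv[["hi"]] - iv[["lo"]] + 1L,
                  integer(1))
  expect_true(all(sizes >= 5))
  expect_false(98L %in% bp$breaks)
  expect_error(detect_breakpoints(block_similarity(c(4, 4)), 5), "at least")
})

test_that("prototypical scale is the within-interval similarity argmax", {
  sim <- matrix(0.5, 5, 5)
  diag(sim) <- 1
  sim[2, ] <- sim[, 2] <- 0.8
  sim[2, 2] <- 1
  expect_equal(prototypical_scale(sim, c(1, 5)), 2)
  expect_equal(prototypical_scale(sim, c(3, 3)), 3) # singleton interval
  # all-identical partitions tie; smallest percentile wins
  expect_equal(prototypical_scale(matrix(1, 6, 6), c(2, 5)), 2)
})

test_that("users contribute to the scales their movement distances fall in", {
  locs <- data.frame(
    location_id = c("A", "B", "C"),
    lat = c(50, 50, 50),
    lon = c(8, 8 + 1 / 111, 9) # ~1 km and ~71 km from A
  )
  scales <- list(
    list(distance_range_km = c(0, 10)),
    list(distance_range_km = c(10, 100))
  )
  asg <- data.frame(
    user_id = c("short", "short", "both", "both", "both", "lone"),
    location_id = c("A", "B", "A", "B", "C", "A")
  )
  out <- user_scale_contributions(asg, locs, scales)
  u <- setNames(out$users$scale_set, out$users$user_id)
  expect_equal(u[["short"]], "1")
  expect_equal(u[["both"]], "12")
  expect_equal(u[["lone"]], "") # no movements at all
  expect_equal(max(out$summary$relative_activity), 1)
  expect_equal(out$summary$n_users[out$summary$scale_set == "12"], 1)
})
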