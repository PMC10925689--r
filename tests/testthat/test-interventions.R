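test_that("remove_edges applies the zero-then-renormalize rule", {
  # removing an already-zero edge on a max-1 matrix is the identity
  W <- matrix(0, 3, 3); W[2, 1] <- 1; W[3, 2] <- 0.4
  C <- connectome(W)
  expect_identical(remove_edges(C, c(3, 1))$weights, C$weights)
  # hand example: w(1->2)=1, w(2->1)=0.5; removing 1->2 leaves w(2->1)=1
  C2 <- two_node_connectome(1, 0.5)
  r <- remove_edges(C2, c(1, 2))
  expect_equal(unname(r$weights[2, 1]), 0)
  expect_equal(unname(r$weights[1, 2]), 1)
  # removing a non-maximal edge preserves ratios of the remaining weights
  C3 <- random_connectome(5, 5, density = 1)
  C3$weights <- C3$weights / max(C3$weights)
  smallest <- which(C3$weights == min(C3$weights[C3$weights > 0]),
                    arr.ind = TRUE)[1, ]
  r3 <- remove_edges(C3, c(smallest["col"], smallest["row"]))
  keep <- C3$weights > 0 & r3$weights > 0
  expect_equal(stats::sd(r3$weights[keep] / C3$weights[keep]), 0,
               tolerance = 1e-12)
  expect_error(remove_edges(two_node_connectome(1, 0),
                            c(1, 2)), "cannot renormalize")
})

test_that("remove_edges zeros the listed entries, restores max 1, idempotent", {
  for (seed in 1:20) {
    C <- random_connectome(6, seed + 40, density = 0.8)
    C$weights <- C$weights / max(C$weights)
    pos <- which(C$weights > 0, arr.ind = TRUE)
    take <- pos[sample(nrow(pos), 2), , drop = FALSE]
    edges <- cbind(take[, "col"], take[, "row"]) # (source, target)
    r <- remove_edges(C, edges)
    expect_true(all(r$weights[cbind(edges[, 2], edges[, 1])] == 0))
    expect_equal(max(r$weights), 1)
    expect_equal(remove_edges(r, edges)$weights, r$weights,
                 tolerance = 1e-12)
    expect_true(all(r$weights >= 0) && all(diag(r$weights) == 0))
    expect_true(all(r$weights[C$weights == 0] == 0)) # zeros stay zero
  }
})

test_that("reduce_outgoing scales the node and preserves total strength", {
  C <- two_node_connectome(1, 1)
  expect_identical(reduce_outgoing(C, 1, 0)$weights, C$weights)
  r <- reduce_outgoing(C, 1, 0.5)
  expect_equal(unname(r$weights[2, 1]), 2 / 3)
  expect_equal(unname(r$weights[1, 2]), 4 / 3)
  expect_equal(sum(r$weights), 2)
  expect_error(reduce_outgoing(C, 1, 1.2), "fraction")
  expect_error(reduce_outgoing(C, 3, 0.5), "out of range")
  W1 <- matrix(0, 2, 2); W1[2, 1] <- 1
  expect_error(reduce_outgoing(connectome(W1), 1, 1),
               "zero total strength")
})

test_that("reduce_outgoing contracts hold for random (C, node, p)", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(3:8, 1)
    C <- random_connectome(n, seed + 70, density = 0.6)
    node <- sample(n, 1)
    p <- stats::runif(1)
    r <- reduce_outgoing(C, node, p)
    expect_lt(abs(sum(r$weights) - sum(C$weights)), 1e-12 * sum(C$weights))
    expect_true(all(r$weights >= 0) && all(diag(r$weights) == 0))
    expect_identical(r$weights == 0, C$weights == 0)
    # node's strongest outgoing weight equals (1-p) * rescale * before
    resc <- sum(C$weights) /
      (sum(C$weights) - p * sum(C$weights[, node]))
    expect_equal(max_outgoing_weight(r, node),
                 (1 - p) * resc * max_outgoing_weight(C, node),
                 tolerance = 1e-10)
  }
  # strictly decreasing in p over a grid
  C <- random_connectome(6, 99, density = 0.7)
  mows <- vapply(seq(0, 0.9, 0.1), function(p)
    max_outgoing_weight(reduce_outgoing(C, 2, p), 2), numeric(1))
  expect_true(all(diff(mows) < 0))
})

test_that("intervention_report lists changes and threshold crossings", {
  C <- random_connectome(5, 13, density = 1)
  C$weights <- C$weights / max(C$weights)
  same <- intervention_report(C, C)
  expect_equal(nrow(same$changed), 0L)
  expect_equal(same$rescale_factor, 1)

  pos <- which(C$weights == max(C$weights), arr.ind = TRUE)[1, ]
  edge <- c(pos["col"], pos["row"])
  r <- remove_edges(C, edge)
  rep1 <- intervention_report(C, r, w_lower = 0.22, w_upper = 0.31)
  expect_true(any(rep1$changed$source == edge[1] &
                  rep1$changed$target == edge[2]))
  expect_false(is.na(rep1$rescale_factor))
  expect_true(all(c("crossed_w_upper", "crossed_w_lower") %in%
                  names(rep1$node_deltas)))
  expect_error(intervention_report(C, random_connectome(4, 1)),
               "different shapes")
})

test_that("apply_intervention dispatches on the spec kind", {
  C <- random_connectome(4, 55, density = 1)
  C$weights <- C$weights / max(C$weights)
  s1 <- intervention_spec("remove_edges", edges = c(1, 2))
  s2 <- intervention_spec("reduce_outgoing", node = 3, p = 0.4)
  expect_equal(apply_intervention(C, s1)$weights,
               remove_edges(C, c(1, 2))$weights)
  expect_equal(apply_intervention(C, s2)$weights,
               reduce_outgoing(C, 3, 0.4)$weights)
  expect_error(intervention_spec("remove_edges"), "edge list")
  expect_error(intervention_spec("reduce_outgoing", node = 1), "node and p")
})
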