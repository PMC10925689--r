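# a 3-node chain: node 1 projects strongly to node 2 (recruiting strength),
# node 2 weakly to node 3; node 3 has no outgoing edges
chain3 <- function() {
  W <- matrix(0, 3, 3)
  W[2, 1] <- 0.7
  W[3, 2] <- 0.05
  connectome(W)
}

test_that("ez_sweep recruits along strong edges and is deterministic", {
  p <- quick_params(duration = 4000)
  sw <- ez_sweep(chain3(), 1, p)
  expect_equal(sw$recruited_count, 1L) # only the strong 1->2 edge recruits
  expect_equal(sw$recruited_fraction, 0.5)
  expect_false(sw$failed)
  expect_equal(sw$ez_max_out_weight, 0.7)
  sw2 <- ez_sweep(chain3(), 1, p)
  expect_identical(sw, sw2) # pipeline determinism under identical seeds

  # an EZ with no outgoing weight cannot recruit anyone
  sw3 <- ez_sweep(chain3(), 3, p)
  expect_equal(sw3$recruited_count, 0L)
  expect_equal(sw3$propagation_class, "localized")
})

test_that("a run whose EZ never seizes is flagged, not fatal", {
  p <- quick_params(duration = 2000)
  sw <- ez_sweep(chain3(), 1, p, x0_ez = -2.1) # healthy everywhere
  expect_true(sw$failed)
  expect_true(is.na(sw$propagation_class))
})

test_that("weight thresholds follow their defining extrema", {
  mk <- function(w, cls) data.frame(
    connectome_id = "c", ez_node = seq_along(w), ez_label = "x",
    seed = 1, recruited_count = 0, recruited_fraction = 0,
    propagation_class = cls, ez_max_out_weight = w, ez_out_degree = 1,
    ez_eig_centrality = 1, ez_avg_shortest_path = 1, failed = FALSE)
  sw <- mk(c(0.10, 0.25, 0.30, 0.50),
           c("localized", "widespread", "localized", "widespread"))
  th <- estimate_weight_thresholds(sw)
  expect_equal(th$w_upper, 0.30)
  expect_equal(th$w_lower, 0.25)
  # defining property on its own input: nothing localized above w_upper,
  # nothing widespread below w_lower
  expect_true(all(sw$ez_max_out_weight[sw$propagation_class == "localized"]
                  <= th$w_upper))
  expect_true(all(sw$ez_max_out_weight[sw$propagation_class == "widespread"]
                  >= th$w_lower))

  th2 <- estimate_weight_thresholds(
    mk(c(0.1, 0.4), c("localized", "widespread")))
  expect_equal(th2$w_upper, 0.1)
  expect_equal(th2$w_lower, 0.4)

  th3 <- estimate_weight_thresholds(mk(c(0.1, 0.2),
                                       c("localized", "localized")))
  expect_true(is.na(th3$w_lower))
  expect_equal(th3$w_upper, 0.2)

  expect_warning(estimate_weight_thresholds(
    mk(c(0.1, 0.3, 0.5), c("localized", "partial", "widespread"))),
    "partial")
})

test_that("evaluate_interventions includes a matching baseline row", {
  p <- quick_params(duration = 4000)
  ev <- evaluate_interventions(chain3(), 1, list(), p)
  expect_equal(nrow(ev), 1L)
  direct <- ez_sweep(chain3(), 1, p)
  expect_equal(ev$recruited_fraction, direct$recruited_fraction)
  expect_equal(ev$propagation_class, direct$propagation_class)

  # removing every outgoing edge of the EZ disconnects it outward
  ev2 <- evaluate_interventions(
    chain3(), 1,
    list(intervention_spec("remove_edges", edges = c(1, 2))), p)
  expect_equal(ev2$recruited_count, c(1L, 0L))
  expect_equal(ev2$propagation_class[2], "localized")
})

test_that("reduction_scan reproduces the baseline at level zero and confines at one", {
  p <- quick_params(duration = 4000)
  rs <- reduction_scan(chain3(), 1, levels = c(0, 1), p)
  base <- ez_sweep(chain3(), 1, p)
  expect_equal(rs$recruited_fraction[1], base$recruited_fraction)
  expect_equal(rs$recruited_fraction[2], 0)
  expect_equal(rs$propagation_class[2], "localized")
  expect_true(all(diff(rs$recruited_fraction) <= 0))
  # a single recruited region already counts as localized, so the baseline
  # level 0 is confining on this toy chain
  expect_equal(attr(rs, "minimal_confining_level"), 0)
  expect_error(reduction_scan(chain3(), 1, levels = c(0, 2), p), "levels")
})

test_that("functional connectivity is a proper correlation matrix", {
  set.seed(1)
  n <- 1e4
  lfp <- matrix(stats::rnorm(n * 4), n, 4)
  lfp[, 2] <- lfp[, 1] # identical signals
  traj <- structure(list(times = seq_len(n), lfp = lfp,
                         params = epileptor_params(duration = n)),
                    class = "epileptor_trajectory")
  FC <- functional_connectivity(traj, from = 0)
  expect_equal(FC, t(FC))
  expect_equal(unname(diag(FC)), rep(1, 4))
  expect_equal(unname(FC[1, 2]), 1)
  # independent white noise: off-diagonal within sampling error
  expect_lt(max(abs(FC[cbind(c(1, 3), c(3, 4))])), 0.05)

  lfp2 <- lfp; lfp2[, 3] <- 5 # constant node
  traj2 <- structure(list(times = seq_len(n), lfp = lfp2,
                          params = epileptor_params(duration = n)),
                     class = "epileptor_trajectory")
  expect_warning(FC2 <- functional_connectivity(traj2, from = 0), "constant")
  expect_equal(unname(FC2[3, c(1, 2, 4)]), rep(0, 3))
  expect_equal(unname(FC2[3, 3]), 1)
})

test_that("fc_similarity correlates upper triangles", {
  A <- stats::cor(matrix(stats::rnorm(500), 100, 5))
  expect_equal(fc_similarity(A, A), 1)
  expect_error(fc_similarity(A, diag(4)), "identical dimensions")
  B <- stats::cor(matrix(stats::rnorm(500), 100, 5))
  expect_lt(abs(fc_similarity(A, B)), 1)
})

test_that("simulated FC of a quiet network reflects shared noise structure", {
  C <- random_connectome(3, 17)
  p <- epileptor_params(x0 = -2.1, duration = 500, seed = 3, dt_out = 0.5)
  tr <- simulate_epileptor(C, p)
  FC <- functional_connectivity(tr)
  expect_equal(FC, t(FC))
  expect_equal(unname(diag(FC)), rep(1, 3))
  expect_true(all(is.finite(FC)))
})
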