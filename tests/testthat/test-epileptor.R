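test_that("f1 and f2 match their piecewise definitions", {
  # continuity at the branch point and hand-evaluated branch values
  expect_equal(f1(0, 5, 2), 0)
  expect_equal(f1(0, -5, -2), 0)
  expect_equal(f1(1, 0, 4), 0)
  expect_equal(f1(-1, 99, 99), -4) # (-1)^3 - 3*(-1)^2
  expect_equal(f1(2, 1.3, 4), 2.6)

  expect_equal(f2(-0.5), 0)
  expect_equal(f2(-0.25), 0)
  expect_equal(f2(0), 1.5)
  expect_true(all(f2(seq(-0.25, 2, 0.05)) >= 0))
})

test_that("network_rhs reproduces hand-substituted derivatives", {
  p <- epileptor_params(x0 = -1.6)
  d0 <- network_rhs(rep(0, 6), p)
  expect_equal(drop(d0), c(3.1, 1, 5.12e-4, 1.5, 0.15, 0), tolerance = 1e-12)

  # z = -1 exercises the -0.1 z^7 branch: r*(6.4 + 1 + 0.1)
  s <- c(0, 0, -1, 0, 0, 0)
  expect_equal(network_rhs(s, p)[3, 1], 8e-5 * 7.5, tolerance = 1e-12)
  # z = +1 uses the linear branch
  s2 <- c(0, 0, 1, 0, 0, 0)
  expect_equal(network_rhs(s2, p)[3, 1], 8e-5 * (6.4 - 1), tolerance = 1e-12)
})

test_that("diffusive coupling vanishes on the synchrony manifold", {
  C <- random_connectome(5, 11)
  p <- epileptor_params(x0 = rep(-1.8, 5))
  state <- matrix(rep(c(-1.2, -6, 2.9, -0.2, 0.4, -0.1), 5), nrow = 6)
  coupled <- network_rhs(state, p, C)
  uncoupled <- network_rhs(state, p, NULL)
  expect_equal(coupled, uncoupled, tolerance = 1e-12)
})

test_that("the compiled integrator agrees with the R right-hand side", {
  # one deterministic Heun step recomputed in R
  C <- random_connectome(4, 3)
  p <- quick_params(x0 = c(-1.6, -2.1, -1.9, -2.0), dt = 0.05, duration = 0.05,
                    dt_out = 0.05, warmup = 0)
  init <- matrix(rep(interictal_state(-2.1, p), 4), nrow = 6)
  init[1, ] <- init[1, ] + c(0.1, -0.05, 0, 0.2) # desynchronize
  tr <- simulate_epileptor(C, p, keep = "all", init = init)
  k1 <- network_rhs(init, p, C)
  pred <- init + p$dt * k1
  k2 <- network_rhs(pred, p, C)
  stepped <- init + p$dt / 2 * (k1 + k2)
  got <- rbind(tr$states$x1[2, ], tr$states$y1[2, ], tr$states$z[2, ],
               tr$states$x2[2, ], tr$states$y2[2, ], tr$states$g[2, ])
  expect_equal(unname(got), unname(stepped), tolerance = 1e-12)
})

test_that("an epileptogenic node seizes and a healthy one stays quiet", {
  p <- quick_params(x0 = -1.6, duration = 8000)
  tr <- simulate_epileptor(NULL, p, n = 1)
  on <- detect_onsets(tr)
  expect_false(is.na(on[1]))
  # full cycle: z rises well above baseline and comes back down
  z <- tr$z[, 1]
  expect_gt(max(z) - z[1], 0.5)
  peak <- which.max(z)
  expect_lt(min(z[peak:length(z)]) - z[1], 0.4)
  # fast-discharge burst visible on the LFP proxy
  expect_gt(max(abs(diff(tr$lfp[, 1]))), 0.5)

  p2 <- quick_params(x0 = -2.1, duration = 6000)
  tr2 <- simulate_epileptor(NULL, p2, n = 1)
  expect_true(is.na(detect_onsets(tr2)[1]))
  expect_lt(max(tr2$z) - min(tr2$z), 0.01)
})

test_that("uncoupled joint simulation equals per-node simulation", {
  x0s <- c(-1.6, -2.1)
  p <- quick_params(x0 = x0s, K = 0, duration = 2000)
  Wd <- matrix(0.5, 2, 2); diag(Wd) <- 0
  joint <- simulate_epileptor(connectome(Wd), p) # K = 0 kills the edges
  for (i in 1:2) {
    pi <- quick_params(x0 = x0s[i], K = 0, duration = 2000)
    single <- simulate_epileptor(NULL, pi, n = 1)
    expect_equal(unname(joint$z[, i]), unname(single$z[, 1]),
                 tolerance = 1e-12)
  }
  # two identical uncoupled nodes follow identical trajectories
  p3 <- quick_params(x0 = c(-1.6, -1.6), K = 0, duration = 2000)
  tr3 <- simulate_epileptor(NULL, p3, n = 2)
  expect_identical(tr3$z[, 1], tr3$z[, 2])
})

test_that("noise-free runs are bit-reproducible and permutation-equivariant", {
  C <- random_connectome(4, 8)
  p <- quick_params(x0 = c(-1.6, -2.1, -2.1, -2.1), duration = 1500)
  a <- simulate_epileptor(C, p)
  b <- simulate_epileptor(C, p)
  expect_identical(a$z, b$z)

  perm <- c(3, 1, 4, 2)
  Cp <- connectome(C$weights[perm, perm])
  pp <- quick_params(x0 = p$x0[perm], duration = 1500)
  tp <- simulate_epileptor(Cp, pp)
  expect_equal(unname(tp$z), unname(a$z[, perm]), tolerance = 1e-12)
})

test_that("stochastic runs reproduce under a fixed seed and differ across seeds", {
  C <- random_connectome(3, 2)
  p <- epileptor_params(x0 = -2.1, duration = 300, seed = 42, dt_out = 1)
  a <- simulate_epileptor(C, p)
  b <- simulate_epileptor(C, p)
  expect_identical(a$lfp, b$lfp)
  p2 <- epileptor_params(x0 = -2.1, duration = 300, seed = 43, dt_out = 1)
  expect_false(identical(simulate_epileptor(C, p2)$lfp, a$lfp))
})

test_that("seizing is monotone in x0 and the interictal state is a fixed point", {
  grid <- seq(-2.2, -1.6, by = 0.1)
  seizing <- vapply(grid, function(x0) {
    p <- quick_params(x0 = x0, duration = 6000)
    !is.na(detect_onsets(simulate_epileptor(NULL, p, n = 1))[1])
  }, logical(1))
  expect_true(all(diff(seizing) >= 0)) # no quiet value above a seizing one

  fp <- interictal_state(-2.1)
  d <- network_rhs(fp, epileptor_params(x0 = -2.1))
  expect_lt(max(abs(d)), 1e-8)
})

test_that("integration blow-up raises an informative error", {
  p <- quick_params(x0 = -1.6, duration = 10, dt_out = 1, warmup = 0)
  init <- matrix(1e8, 6, 1)
  expect_error(simulate_epileptor(NULL, p, n = 1, init = init), "blew up")
})

test_that("trajectory arrays are finite with uniformly spaced times", {
  C <- random_connectome(3, 9)
  p <- epileptor_params(x0 = c(-1.6, -2.1, -2.1), duration = 500, dt_out = 0.5)
  tr <- simulate_epileptor(C, p)
  expect_true(all(is.finite(tr$z)) && all(is.finite(tr$lfp)))
  expect_equal(unique(round(diff(tr$times), 10)), 0.5)
})
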