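test_that("time-averaged relative error matches hand values and homogeneity", {
  u <- matrix(c(3, 4), 2, 1)
  up <- matrix(c(3, 0), 2, 1)
  expect_equal(eps_rel(u, up), 4 / 5)
  expect_equal(eps_rel(u, u), 0)
  expect_equal(eps_rel(10 * u, 10 * up), eps_rel(u, up))
  # mean over instances
  expect_equal(eps_rel(list(u, u), list(up, u)), 0.4)
  expect_error(eps_rel(matrix(0, 2, 1), up), "zero-norm")
})

test_that("per-node error fields match their printed normalizations", {
  U <- matrix(c(0, 1), 2, 1)  # Nt = 1, ||u^1|| = 1
  e <- eps_k(U[, 1], c(0, 0.9), U)
  expect_equal(e, c(0, 0.1))
  expect_equal(eps_k(U[, 1], U[, 1], U), c(0, 0))
  # scale invariance
  expect_equal(eps_k(2 * U[, 1], 2 * c(0, 0.9), 2 * U), e)
  # percent field with 1-norm normalization
  es <- eps_ks(c(1, 1), c(1, 0.98))
  expect_equal(es, c(0, 1))
  expect_equal(eps_ks(c(1, 1), c(1, 1)), c(0, 0))
  expect_error(eps_ks(c(0, 0), c(1, 1)), "1-norm")
})

test_that("activation times interpolate threshold crossings linearly", {
  # u = 0 at t~ = 10 ms, u = 1 at t~ = 11 ms, threshold 0.5 -> 10.5 ms
  U <- rbind(c(0, 1), c(0, 0))
  times <- c(10, 11) / 12.9
  am <- activation_map(U, times, threshold = 0.5)
  expect_equal(am$t_act_ms[1], 10.5)
  expect_true(is.na(am$t_act_ms[2]))  # never crosses -> sentinel
  # node above threshold from the start activates at the first sample
  U2 <- rbind(c(0.9, 0.9))
  expect_equal(activation_map(U2, times)$t_act_ms, 10)
})

test_that("activation times increase with distance on an isotropic slab", {
  g <- grid2d(15, 15, 4, 4)
  ion <- ionic_params()
  sc <- scenario(
    "iso", g, time_grid(0.2 / 12.9, 40, Nt = 80),
    ionic_builder = function(mu) ion,
    conductivity_builder = function(mu) conductivity_model(1.29, 1.29),
    stimulus_builder = function(mu)
      list(gaussian_stimulus(C = 100, beta_cm2 = 0.05, center = c(0, 0))),
    param_box = rbind(0, 1))
  tr <- solve_fom(sc, 0.5)
  am <- activation_map(tr$U, tr$times)
  r <- sqrt(g$x^2 + g$y^2)
  act <- !is.na(am$t_act_ms)
  expect_gt(mean(act), 0.5)
  # binned by radius, mean activation time weakly increases
  bins <- cut(r[act], breaks = seq(0, max(r), length.out = 6))
  mt <- tapply(am$t_act_ms[act], bins, mean)
  mt <- mt[!is.na(mt)]
  expect_true(all(diff(mt) > -1e-9))
})

test_that("APD accumulates time above threshold with partial intervals", {
  times <- (0:4) / 12.9  # 1 ms sample spacing
  # node 1: above threshold on [1, 3] ms exactly at samples
  U <- rbind(c(0, 1, 1, 1, 0), c(0, 0, 0, 0, 0))
  apd <- apd_map(U, times, threshold = 0.5)
  # rises crossing 0.5 at 0.5 ms, falls at 3.5 ms -> 3 ms above
  expect_equal(apd[1], 3)
  expect_equal(apd[2], 0)
})
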