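test_that("ischemic modulation matches its closed form and limits", {
  m <- ischemic_modulation(5, 5, c(5, 5))
  expect_equal(m$rho, 0)
  expect_equal(m$sigma, 1e-4)
  far <- ischemic_modulation(1e3, 1e3, c(5, 5))
  expect_equal(far$rho, 1)
  expect_equal(far$sigma, 1)
  # x = (mu1 + 1, mu2), alpha = 7: rho = 1 - exp(-1/98)
  off <- ischemic_modulation(6, 5, c(5, 5), alpha = 7)
  expect_equal(off$rho, 1 - exp(-1 / 98), tolerance = 1e-12)
  # range invariant over a sweep of points
  pts <- expand.grid(x = seq(0, 10, 0.5), y = seq(0, 10, 0.5))
  mm <- ischemic_modulation(pts$x, pts$y, c(4.2, 5.9))
  expect_true(all(mm$rho >= 0 & mm$rho < 1))
  expect_true(all(mm$sigma >= 1e-4 & mm$sigma <= 1))
})

test_that("ischemic-slab preset reproduces the printed constants", {
  sc <- build_test1()
  expect_equal(sc$grid$N, 64 * 64)
  expect_equal(sc$grid$Lx, 10)
  expect_equal(sc$time$dt, 0.1 / 12.9)
  expect_equal(sc$time$n_steps, 4000)
  expect_equal(sc$time$Nt, 1000)
  expect_equal(unname(sc$param_box), rbind(c(3.5, 3.5), c(6.5, 6.5)))
  ion <- sc$ionic_builder(c(5, 5))
  expect_equal(unclass(ion)[c("K", "a", "b", "eps0", "c1", "c2")],
               list(K = 8, a = 0.01, b = 0.15, eps0 = 0.002, c1 = 0.2, c2 = 0.3))
  cond <- sc$conductivity_builder(c(5, 5))
  expect_equal(cond$sigma_l, 12.9 * 0.2)
  expect_equal(cond$sigma_t, 12.9 * 0.1)
  # training lattice (3.5 + 0.5 i, 3.5 + 0.5 j), i, j = 0..6 -> 49 points
  expect_equal(nrow(sc$train_params), 49)
  expect_equal(sort(unique(sc$train_params[, 1])), 3.5 + 0.5 * (0:6))
  # testing lattice (3.75 + 0.5 i, ...), i = 0..5 -> 36 points
  expect_equal(nrow(sc$test_params), 36)
  expect_equal(sort(unique(sc$test_params[, 2])), 3.75 + 0.5 * (0:5))
  # stimulus: C = 100 at the origin inside [0, 2] ms, off at 3 ms
  stim <- stimulus_evaluator(sc$stimulus_builder(c(5, 5)), sc$grid)
  expect_equal(stim(1 / 12.9)[1], 100)
  expect_equal(max(stim(3 / 12.9)), 0)
})

test_that("re-entry preset implements the S1-S2 protocol", {
  sc <- build_test2(variant = "full", nx = 32, Nt = 40, n_train = 13)
  expect_equal(unname(sc$param_box), rbind(0.5, 1.1))
  expect_equal(nrow(sc$train_params), 13)
  expect_equal(nrow(sc$test_params), 12)
  expect_equal(unname(sc$test_params[1, 1]),
               mean(sc$train_params[1:2, 1]))
  # snapshot window restricted to [95, 175] ms
  t_ms <- 12.9 * sc$time$sample_times
  expect_true(all(t_ms >= 95 & t_ms <= 175))
  ion <- sc$ionic_builder(0.9)
  expect_equal(ion$a, 0.1)
  expect_equal(ion$c1, 0.14)
  cond <- sc$conductivity_builder(0.9)
  expect_equal(cond$sigma_l, 2e-3)
  expect_equal(cond$sigma_t, 3.1e-4)
  stims <- sc$stimulus_builder(0.9)
  ev <- stimulus_evaluator(stims, sc$grid)
  node_s1 <- nearest_node(sc$grid, c(1, 0.05))
  node_s2 <- nearest_node(sc$grid, c(1, 0.9))
  node_out <- nearest_node(sc$grid, c(1, 0.9 + 0.3))
  expect_equal(ev(3 / 12.9)[node_s1], 1)      # S1 active at 3 ms
  expect_equal(ev(72 / 12.9)[node_s2], 1)     # S2 active at 72 ms
  expect_equal(ev(72 / 12.9)[node_out], 0)    # outside the S2 disk
  expect_equal(ev(50 / 12.9)[node_s1], 0)     # between the stimuli
  # reentry_only variant narrows the box
  expect_equal(unname(build_test2("reentry_only", nx = 16, Nt = 10,
                                  n_train = 3)$param_box), rbind(0.8, 1.1))
})

test_that("restitution preset parametrizes conductivities and gating", {
  sc <- build_test4(nx = 16, Nt = 20)
  expect_equal(nrow(sc$train_params), 125)
  expect_equal(nrow(sc$test_params), 16)
  expect_equal(unname(sc$param_box[, 1]), 12.9 * c(0.06, 0.2))
  expect_equal(unname(sc$param_box[, 3]), c(0.15, 0.25))
  expect_equal(sort(unique(sc$train_params[, 3])), 0.15 + 0.025 * (0:4))
  # mu3 replaces c1
  ion <- sc$ionic_builder(c(1.5, 0.9, 0.21))
  expect_equal(ion$c1, 0.21)
  # mu1 = mu2 gives an isotropic tensor
  g <- grid2d(3, 3, 1, 1)
  et <- cardioROM:::element_tensor(g, sc$conductivity_builder(c(1.1, 1.1, 0.2)))
  expect_equal(et$dxx, rep(1.1, 4))
  expect_equal(et$dyy, rep(1.1, 4))
  expect_equal(et$dxy, rep(0, 4))
})

test_that("parameter grids are deterministic and stay inside the box", {
  box <- rbind(c(0, 10), c(1, 20))
  lat <- make_parameter_grid(box, list(type = "lattice", counts = c(1, 1),
                                       offsets = c(0.2, 3)))
  expect_equal(unname(lat), matrix(c(0.2, 13), 1))
  u1 <- make_parameter_grid(box, list(type = "uniform", n = 5, seed = 9))
  u2 <- make_parameter_grid(box, list(type = "uniform", n = 5, seed = 9))
  expect_identical(u1, u2)
  expect_true(all(u1[, 1] >= 0 & u1[, 1] <= 1))
  expect_error(make_parameter_grid(box, list(type = "lattice", counts = c(2, 2),
                                             steps = c(5, 30))), "outside")
})

test_that("scenario configs round-trip through YAML", {
  for (name in c("test1-mini", "test2-reentry", "test4-mini")) {
    sc <- load_scenario(name)
    cfg <- scenario_to_config(sc)
    path <- tempfile(fileext = ".yaml")
    yaml::write_yaml(cfg, path, precision = 15)
    sc2 <- scenario_from_config(yaml::read_yaml(path))
    expect_equal(scenario_to_config(sc2), cfg)
    expect_equal(sc2$grid$N, sc$grid$N)
    expect_equal(sc2$time$sample_times, sc$time$sample_times)
    expect_equal(sc2$train_params, sc$train_params)
    expect_equal(sc2$test_params, sc$test_params)
  }
  expect_error(load_scenario("no-such-preset"), "valid presets")
})
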