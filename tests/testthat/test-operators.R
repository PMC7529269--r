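test_that("stiffness annihilates constants and lumped mass conserves area", {
  g <- grid2d(7, 5, 3, 2)
  ops <- assemble_operators(g, conductivity_model(1, 1))
  expect_lt(max(abs(ops$stiffness %*% rep(1, g$N))), 1e-12)
  expect_equal(sum(ops$mass), 3 * 2, tolerance = 1e-12)
  expect_true(all(ops$mass > 0))

  # anisotropic + modulated case keeps both properties (uniform modulation)
  ops2 <- assemble_operators(
    g, conductivity_model(2.58, 1.29, f0 = c(1, 0),
                          modulation = rep(0.5, g$N)))
  expect_lt(max(abs(ops2$stiffness %*% rep(1, g$N))), 1e-12)
  expect_equal(sum(ops2$mass), 6, tolerance = 1e-12)
})

test_that("assembly matches an independent dense quadrature oracle", {
  g <- grid2d(3, 3, 2, 2)  # unit spacing
  for (cond in list(
    conductivity_model(1, 1),
    conductivity_model(2.58, 1.29, f0 = c(1, 0)),
    conductivity_model(1.7, 0.6, f0 = c(1, 1) / sqrt(2)))) {
    A <- as.matrix(assemble_operators(g, cond)$stiffness)
    A_ref <- dense_stiffness_oracle(g, cond)
    expect_lt(max(abs(A - A_ref)), 1e-9)
  }
  expect_equal(assemble_operators(g, conductivity_model(1, 1))$mass,
               dense_mass_oracle(g), tolerance = 1e-10)
})

test_that("stiffness is symmetric and PSD", {
  g <- grid2d(5, 6, 1.2, 0.8)
  A <- assemble_operators(g, conductivity_model(2, 0.5, f0 = c(0, 1)))$stiffness
  expect_lt(max(abs(A - Matrix::t(A))), 1e-14)
  ev <- eigen(as.matrix(A), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
})

test_that("invalid conductivity inputs are rejected", {
  expect_error(conductivity_model(1, -1))
  expect_error(conductivity_model(0.5, 1), "strict")
  expect_error(conductivity_model(1, 0.5, f0 = c(2, 0)), "unit")
  expect_error(conductivity_model(1, 0.5, modulation = 1.5), "modulation")
  expect_silent(conductivity_model(0.5, 1, strict = FALSE))
})
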