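# Independent reference implementations used as oracles. These deliberately
# avoid the package's assembly/stepping code paths: dense matrices, explicit
# basis-function formulas, and brute-force midpoint quadrature.

# Dense Q1 stiffness by composite Simpson quadrature (exact for the
# piecewise-quadratic integrand, and a different rule from the implementation).
dense_stiffness_oracle <- function(grid, cond) {
  N <- grid$N
  A <- matrix(0, N, N)
  hx <- grid$hx; hy <- grid$hy
  et <- cardioROM:::element_tensor(grid, cond)
  qs <- c(0, 0.5, 1); qw <- c(1, 4, 1) / 6
  for (e in seq_len(nrow(et$corners))) {
    nodes <- et$corners[e, ]
    D <- matrix(c(et$dxx[e], et$dxy[e], et$dxy[e], et$dyy[e]), 2, 2)
    Ke <- matrix(0, 4, 4)
    for (i in 1:3) for (j in 1:3) {
      xi <- qs[i]; eta <- qs[j]
      # gradients of (1-xi)(1-eta), xi(1-eta), (1-xi)eta, xi*eta
      Gx <- c(-(1 - eta), (1 - eta), -eta, eta) / hx
      Gy <- c(-(1 - xi), -xi, (1 - xi), xi) / hy
      B <- rbind(Gx, Gy)
      Ke <- Ke + t(B) %*% D %*% B * (hx * hy * qw[i] * qw[j])
    }
    A[nodes, nodes] <- A[nodes, nodes] + Ke
  }
  A
}

# Dense lumped mass by the same quadrature (row sums of the consistent mass).
dense_mass_oracle <- function(grid) {
  m <- numeric(grid$N)
  et <- cardioROM:::element_tensor(grid, conductivity_model(1, 1))
  qs <- c(0, 0.5, 1); qw <- c(1, 4, 1) / 6
  phi_int <- numeric(4)
  for (i in 1:3) for (j in 1:3) {
    xi <- qs[i]; eta <- qs[j]
    phi <- c((1 - xi) * (1 - eta), xi * (1 - eta), (1 - xi) * eta, xi * eta)
    phi_int <- phi_int + phi * (grid$hx * grid$hy * qw[i] * qw[j])
  }
  for (e in seq_len(nrow(et$corners)))
    m[et$corners[e, ]] <- m[et$corners[e, ]] + phi_int
  m
}

# Naive dense semi-implicit step (base solve, no factorization reuse).
dense_step_oracle <- function(u, w, A_dense, mass, iapp, dt, ionic, rho = 1) {
  w1 <- w - dt * gating_rhs(u, w, ionic)
  sys <- diag(mass / dt) + A_dense
  rhs <- (mass / dt) * u - mass * (rho * ionic_current(u, w1, ionic)) +
    mass * iapp
  list(u = solve(sys, rhs), w = w1)
}

# Small helper: a fast-to-solve FOM scenario for unit tests (no scar).
tiny_slab_scenario <- function(nx = 16, T_ms = 50, Nt = 25) {
  g <- grid2d(nx, nx, 10, 10)
  ion <- ionic_params()
  box <- rbind(c(3.5, 3.5), c(6.5, 6.5))
  scenario(
    name = "tiny-slab", grid = g, time = time_grid(0.2 / 12.9, T_ms, Nt),
    ionic_builder = function(mu) ion,
    conductivity_builder = function(mu)
      conductivity_model(12.9 * 0.2, 12.9 * 0.1, f0 = c(1, 0)),
    stimulus_builder = function(mu)
      list(gaussian_stimulus(C = 100, beta_cm2 = 0.02, center = c(0, 0))),
    param_box = box)
}
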