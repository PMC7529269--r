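# Conductivity tensor and applied-current (stimulus) descriptions.

#' Anisotropic conductivity model
#'
#' The tensor is `D(x) = sigma_t I + (sigma_l - sigma_t) f0 f0^T`, optionally
#' multiplied by a scalar modulation field `sigma(x) in (0, 1]` (used to model
#' non-conductive ischemic tissue). Conductivities are the coefficients of the
#' rescaled-time equation, in cm^2/ms of rescaled time, stored exactly as
#' printed in the benchmark definitions (e.g. `12.9 * 0.1`).
#'
#' @param sigma_l,sigma_t longitudinal / transversal conductivities,
#'   `sigma_l >= sigma_t > 0`
#' @param f0 unit fiber direction: length-2 vector (constant field) or an
#'   N x 2 matrix of per-node directions
#' @param modulation scalar 1 or length-N field in (0, 1]
#' @param strict require `sigma_l >= sigma_t` (the physiological ordering);
#'   set `FALSE` for parameter sweeps in which the axial symmetry of the
#'   tensor is kept but the ordering may flip
#' @return object of class `conductivity_model`
#' @export
conductivity_model <- function(sigma_l, sigma_t, f0 = c(1, 0), modulation = 1,
                               strict = TRUE) {
  stopifnot(sigma_t > 0, sigma_l > 0)
  if (strict && sigma_l < sigma_t)
    stop("sigma_l < sigma_t; pass strict = FALSE for non-physiological sweeps")
  if (is.matrix(f0)) {
    nrm <- sqrt(rowSums(f0^2))
    if (any(abs(nrm - 1) > 1e-8)) stop("fiber vectors must have unit norm")
  } else {
    if (abs(sqrt(sum(f0^2)) - 1) > 1e-8) stop("fiber vector must have unit norm")
  }
  if (any(modulation <= 0) || any(modulation > 1))
    stop("modulation field must lie in (0, 1]")
  structure(list(sigma_l = sigma_l, sigma_t = sigma_t, f0 = f0,
                 modulation = modulation),
            class = "conductivity_model")
}

# Per-element 2x2 tensor components (dxx, dxy, dyy), modulation included.
# Elements are the (nx-1) x (ny-1) cells; nodal fields are averaged per cell.
element_tensor <- function(grid, cond) {
  nex <- grid$nx - 1L; ney <- grid$ny - 1L
  nE <- nex * ney
  # indices of the 4 corner nodes of each element (x fastest)
  i <- rep(seq_len(nex), times = ney)
  j <- rep(seq_len(ney), each = nex)
  n1 <- i + (j - 1L) * grid$nx
  corners <- cbind(n1, n1 + 1L, n1 + grid$nx, n1 + grid$nx + 1L)

  if (length(cond$modulation) == 1) {
    sig <- rep(cond$modulation, nE)
  } else {
    stopifnot(length(cond$modulation) == grid$N)
    m <- cond$modulation
    sig <- (m[corners[, 1]] + m[corners[, 2]] + m[corners[, 3]] + m[corners[, 4]]) / 4
  }
  if (is.matrix(cond$f0)) {
    f <- (cond$f0[corners[, 1], , drop = FALSE] + cond$f0[corners[, 2], , drop = FALSE] +
          cond$f0[corners[, 3], , drop = FALSE] + cond$f0[corners[, 4], , drop = FALSE]) / 4
    f <- f / sqrt(rowSums(f^2))
    fx <- f[, 1]; fy <- f[, 2]
  } else {
    fx <- rep(cond$f0[1], nE); fy <- rep(cond$f0[2], nE)
  }
  dl <- cond$sigma_l - cond$sigma_t
  list(
    corners = corners,
    dxx = sig * (cond$sigma_t + dl * fx * fx),
    dxy = sig * (dl * fx * fy),
    dyy = sig * (cond$sigma_t + dl * fy * fy)
  )
}

#' Applied-current term
#'
#' A stimulus is a nonnegative spatial profile active during a dimensional
#' time window `[t_on_ms, t_off_ms]` (the window is specified in ms and tested
#' against the dimensional time `12.9 t`). Amplitudes are dimensionless source
#' magnitudes in the nondimensional equation.
#'
#' @param profile function `(x, y) -> nonnegative amplitude`, vectorized
#' @param t_on_ms,t_off_ms activity window in ms, `t_off_ms > t_on_ms`
#' @param label optional name
#' @return object of class `stimulus_term`
#' @export
stimulus_term <- function(profile, t_on_ms, t_off_ms, label = "stim") {
  stopifnot(is.function(profile), t_off_ms > t_on_ms)
  structure(list(profile = profile, t_on_ms = t_on_ms, t_off_ms = t_off_ms,
                 label = label),
            class = "stimulus_term")
}

#' Gaussian stimulus `C exp(-||x - center||^2 / beta)` on a time window
#' @param C amplitude
#' @param beta_cm2 Gaussian width parameter (cm^2)
#' @param center length-2 center (cm)
#' @param t_on_ms,t_off_ms window (ms)
#' @export
gaussian_stimulus <- function(C, beta_cm2, center = c(0, 0),
                              t_on_ms = 0, t_off_ms = 2) {
  stopifnot(C >= 0, beta_cm2 > 0)
  stimulus_term(
    function(x, y) C * exp(-((x - center[1])^2 + (y - center[2])^2) / beta_cm2),
    t_on_ms, t_off_ms, label = "gaussian"
  )
}

#' Indicator stimulus: `amplitude` on a region, 0 elsewhere
#' @param region function `(x, y) -> logical`, vectorized
#' @param amplitude value inside the region
#' @param t_on_ms,t_off_ms window (ms)
#' @param label optional name
#' @export
indicator_stimulus <- function(region, amplitude = 1, t_on_ms, t_off_ms,
                               label = "indicator") {
  stimulus_term(function(x, y) amplitude * as.numeric(region(x, y)),
                t_on_ms, t_off_ms, label = label)
}

#' Evaluate a list of stimuli as nodal applied current at rescaled time t
#'
#' @param stims list of `stimulus_term`
#' @param grid a `grid2d`
#' @return function `t -> length-N applied-current vector`; the nodal profiles
#'   are precomputed once
#' @export
stimulus_evaluator <- function(stims, grid) {
  profiles <- lapply(stims, function(s) s$profile(grid$x, grid$y))
  windows <- lapply(stims, function(s) c(s$t_on_ms, s$t_off_ms))
  force(profiles); force(windows)
  N <- grid$N
  function(t) {
    t_ms <- TIME_SCALE_MS * t
    out <- numeric(N)
    for (k in seq_along(profiles)) {
      if (t_ms >= windows[[k]][1] && t_ms <= windows[[k]][2])
        out <- out + profiles[[k]]
    }
    out
  }
}
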