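# Structured grids and time discretization.
#
# All internal arithmetic uses the rescaled (dimensionless) time t = t_ms / 12.9;
# see `to_dimensional()` for the affine maps back to ms and mV.

#' Rescaling constants
#'
#' The model is integrated in dimensionless variables; dimensional time and
#' potential are recovered as `t_ms = 12.9 * t` and `u_mV = 100 * u - 80`,
#' so u = 0 is the resting state (-80 mV) and u = 1 the excited state (+20 mV).
#' @name rescaling
NULL

TIME_SCALE_MS <- 12.9

#' Create a 2D structured grid
#'
#' Nodes are ordered lexicographically: x runs fastest, i.e. node index
#' `(i, j)` (1-based, i along x, j along y) maps to `i + (j - 1) * nx`.
#'
#' @param nx,ny node counts per axis (>= 2)
#' @param Lx,Ly side lengths in cm
#' @return an object of class `grid2d` with fields `nx, ny, Lx, Ly, N, hx, hy`
#'   and node coordinate vectors `x`, `y` (length N)
#' @export
grid2d <- function(nx, ny, Lx, Ly) {
  stopifnot(nx >= 2, ny >= 2, Lx > 0, Ly > 0)
  nx <- as.integer(nx); ny <- as.integer(ny)
  hx <- Lx / (nx - 1)
  hy <- Ly / (ny - 1)
  xs <- seq(0, Lx, length.out = nx)
  ys <- seq(0, Ly, length.out = ny)
  g <- list(
    nx = nx, ny = ny, Lx = Lx, Ly = Ly,
    N = nx * ny, hx = hx, hy = hy,
    x = rep(xs, times = ny),
    y = rep(ys, each = nx)
  )
  class(g) <- "grid2d"
  g
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("grid2d: %d x %d nodes (N = %d) on (0, %g) x (0, %g) cm, h = (%.4g, %.4g)\n",
              x$nx, x$ny, x$N, x$Lx, x$Ly, x$hx, x$hy))
  invisible(x)
}

#' Create a time grid
#'
#' @param dt time step in rescaled units
#' @param T_ms final time in ms
#' @param Nt number of snapshot sample times (uniformly spread over the
#'   snapshot window); defaults to the number of steps
#' @param window_ms optional snapshot window `c(t_start_ms, t_end_ms)`;
#'   snapshots are sampled only inside it (default: the whole interval)
#' @return object of class `time_grid` with `dt`, `T_ms`, `n_steps`,
#'   `sample_steps` (step indices at which snapshots are taken) and
#'   `sample_times` (rescaled times `k * dt`)
#' @export
time_grid <- function(dt, T_ms, Nt = NULL, window_ms = NULL) {
  stopifnot(dt > 0, T_ms > 0)
  T_resc <- T_ms / TIME_SCALE_MS
  n_steps <- as.integer(round(T_resc / dt))
  if (is.null(window_ms)) window_ms <- c(0, T_ms)
  stopifnot(length(window_ms) == 2, window_ms[1] < window_ms[2])
  if (is.null(Nt)) Nt <- n_steps
  Nt <- as.integer(Nt)
  stopifnot(Nt >= 1, Nt <= n_steps)
  # candidate steps whose times fall inside the window
  step_times_ms <- (seq_len(n_steps) * dt) * TIME_SCALE_MS
  tol <- 1e-9 * max(1, abs(window_ms[2]))
  in_win <- which(step_times_ms >= window_ms[1] - tol &
                    step_times_ms <= window_ms[2] + tol)
  if (length(in_win) < Nt)
    stop("snapshot window too narrow for the requested Nt")
  sample_steps <- if (Nt == 1) in_win[length(in_win)] else
    in_win[unique(round(seq(1, length(in_win), length.out = Nt)))]
  tg <- list(
    dt = dt, T_ms = T_ms, n_steps = n_steps, Nt = length(sample_steps),
    window_ms = window_ms,
    sample_steps = as.integer(sample_steps),
    sample_times = sample_steps * dt
  )
  class(tg) <- "time_grid"
  tg
}

#' Convert dimensionless potential/time to dimensional units
#'
#' @param u dimensionless potential (any numeric shape)
#' @param t rescaled time
#' @return list with `u_mV = 100 u - 80` and `t_ms = 12.9 t`
#' @export
to_dimensional <- function(u = NULL, t = NULL) {
  out <- list()
  if (!is.null(u)) out$u_mV <- 100 * u - 80
  if (!is.null(t)) out$t_ms <- TIME_SCALE_MS * t
  out
}

#' Index of the grid node nearest to a point
#' @param grid a `grid2d`
#' @param p numeric length-2 point (cm)
#' @return integer node index
#' @export
nearest_node <- function(grid, p) {
  which.min((grid$x - p[1])^2 + (grid$y - p[2])^2)
}
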