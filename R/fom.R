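# Full-order monodomain solver: semi-implicit (IMEX) first-order stepping.
#
# Scheme per step (diffusion implicit, reaction explicit, gating first):
#   w^{k+1} = w^k - dt * g(u^k, w^k)
#   (M/dt + A) u^{k+1} = (M/dt) u^k - M (rho .* Iion(u^k, w^{k+1})) + M Iapp(t^k)
# with lumped mass M and nodal (collocated) ionic evaluation. The system
# matrix is time-independent per parameter instance, so its sparse Cholesky
# factorization is computed once and reused at every step.

#' Initial (rest) state
#' @param N number of nodes
#' @return list with zero `u`, `w` and `t = 0`
#' @export
rest_state <- function(N) list(u = numeric(N), w = numeric(N), t = 0)

#' Prefactorized linear solver for the semi-implicit step
#' @param ops operators from [assemble_operators()]
#' @param dt time step (rescaled units)
#' @return list with the Cholesky factor and a `solve(b)` closure
#' @export
fom_stepper <- function(ops, dt) {
  S <- Matrix::forceSymmetric(
    Matrix::Diagonal(x = ops$mass / dt) + ops$stiffness)
  ch <- Matrix::Cholesky(S, LDL = FALSE)
  list(chol = ch,
       solve = function(b) as.numeric(Matrix::solve(ch, b, system = "A")))
}

#' One semi-implicit step
#'
#' @param state list `(u, w, t)` (rescaled time)
#' @param ops operators from [assemble_operators()]
#' @param stim applied-current evaluator `t -> vector` (see
#'   [stimulus_evaluator()]) or `NULL` for no stimulus
#' @param dt time step (rescaled)
#' @param ionic `ionic_params`
#' @param rho nodal ionic-current scaling (scalar 1 or length-N vector;
#'   models non-conductive tissue)
#' @param stepper optional prefactorized solver from [fom_stepper()]; built
#'   on the fly if missing
#' @return advanced state
#' @export
semi_implicit_step <- function(state, ops, stim, dt, ionic, rho = 1,
                               stepper = NULL) {
  if (is.null(stepper)) stepper <- fom_stepper(ops, dt)
  u <- state$u; w <- state$w
  w1 <- w - dt * gating_rhs(u, w, ionic)
  iapp <- if (is.null(stim)) 0 else stim(state$t)
  rhs <- (ops$mass / dt) * u - ops$mass * (rho * ionic_current(u, w1, ionic)) +
    ops$mass * iapp
  u1 <- stepper$solve(rhs)
  if (anyNA(u1) || any(!is.finite(u1)))
    stop(sprintf("semi_implicit_step: non-finite potential at t = %g", state$t + dt))
  list(u = u1, w = w1, t = state$t + dt)
}

#' Solve the full-order model for one parameter instance
#'
#' Time-marches from zero initial conditions and samples the trajectory at the
#' time grid's sample steps. Alongside the potential snapshots, the nodal
#' nonlinear term `rho .* Iion(u, w)` is recorded (consumed later by DEIM) as
#' well as the gating snapshots.
#'
#' @param scenario a `scenario` (see [scenario()])
#' @param mu parameter vector inside the scenario's parameter box
#' @param tg optional `time_grid` override (default: the scenario's)
#' @param probes optional list of length-2 points (cm); full-resolution AP
#'   traces are recorded at the nearest nodes
#' @param store_gating keep gating snapshots (default TRUE)
#' @param check_box reject `mu` outside the parameter box (default TRUE)
#' @return object of class `fom_trajectory`: `U` (N x Nt), `W`, `F` (ionic
#'   snapshots), `times` (rescaled), `mu`, and `probes` (data.frame of t_ms
#'   and u_mV columns) when requested
#' @export
solve_fom <- function(scenario, mu, tg = NULL, probes = NULL,
                      store_gating = TRUE, check_box = TRUE) {
  if (is.null(tg)) tg <- scenario$time
  mu <- as.numeric(mu)
  if (check_box && !mu_in_box(mu, scenario$param_box))
    stop("mu outside the scenario parameter box (use check_box = FALSE to override)")

  grid <- scenario$grid
  ionic <- scenario$ionic_builder(mu)
  cond <- scenario$conductivity_builder(mu)
  rho <- scenario$reaction_scaling_builder(mu)
  stim <- stimulus_evaluator(scenario$stimulus_builder(mu), grid)
  ops <- assemble_operators(grid, cond)
  stepper <- fom_stepper(ops, tg$dt)

  N <- grid$N
  Nt <- tg$Nt
  U <- matrix(0, N, Nt)
  W <- if (store_gating) matrix(0, N, Nt) else NULL
  F <- matrix(0, N, Nt)
  probe_idx <- if (!is.null(probes)) vapply(probes, function(p) nearest_node(grid, p), integer(1))
  traces <- if (!is.null(probes)) matrix(0, tg$n_steps, length(probes))

  state <- rest_state(N)
  sample_set <- tg$sample_steps
  next_sample <- 1L
  for (k in seq_len(tg$n_steps)) {
    state <- semi_implicit_step(state, ops, stim, tg$dt, ionic, rho, stepper)
    if (k %% 100L == 0L && any(abs(state$u) > 1e3))
      stop(sprintf("solve_fom: overflow guard tripped at step %d", k))
    if (!is.null(probes)) traces[k, ] <- state$u[probe_idx]
    if (next_sample <= Nt && k == sample_set[next_sample]) {
      U[, next_sample] <- state$u
      if (store_gating) W[, next_sample] <- state$w
      F[, next_sample] <- rho * ionic_current(state$u, state$w, ionic)
      next_sample <- next_sample + 1L
    }
  }

  out <- list(U = U, W = W, F = F, times = tg$sample_times, mu = mu,
              grid = grid, time = tg)
  if (!is.null(probes)) {
    tm <- to_dimensional(t = seq_len(tg$n_steps) * tg$dt)$t_ms
    df <- data.frame(t_ms = tm)
    for (j in seq_along(probes))
      df[[paste0("u_mV_p", j)]] <- to_dimensional(u = traces[, j])$u_mV
    out$probes <- df
    out$probe_nodes <- probe_idx
  }
  class(out) <- "fom_trajectory"
  out
}

#' Build a snapshot set over a list of parameter instances
#'
#' The single exchange object between the solver and both reduced models.
#'
#' @param scenario a `scenario`
#' @param params matrix (rows = parameter instances) or list of vectors
#' @param tg optional `time_grid` override
#' @param ... forwarded to [solve_fom()]
#' @return object of class `snapshot_set` with `S` (N x Nt*Nparams potential
#'   matrix), `F` (matching nonlinear-term snapshots), `W` (gating), `labels`
#'   (data.frame with time and parameter columns) and metadata
#' @export
snapshot_set <- function(scenario, params, tg = NULL, ...) {
  if (is.null(tg)) tg <- scenario$time
  if (is.list(params) && !is.data.frame(params)) params <- do.call(rbind, params)
  params <- as.matrix(params)
  runs <- lapply(seq_len(nrow(params)),
                 function(i) solve_fom(scenario, params[i, ], tg = tg, ...))
  S <- do.call(cbind, lapply(runs, `[[`, "U"))
  F <- do.call(cbind, lapply(runs, `[[`, "F"))
  W <- if (!is.null(runs[[1]]$W)) do.call(cbind, lapply(runs, `[[`, "W"))
  labels <- do.call(rbind, lapply(seq_along(runs), function(i) {
    data.frame(t = runs[[i]]$times, param_id = i,
               matrix(rep(params[i, ], each = tg$Nt), nrow = tg$Nt,
                      dimnames = list(NULL, paste0("mu", seq_len(ncol(params))))))
  }))
  stopifnot(ncol(S) == tg$Nt * nrow(params))
  structure(list(S = S, F = F, W = W, labels = labels, params = params,
                 scenario_name = scenario$name, grid = scenario$grid, time = tg),
            class = "snapshot_set")
}

#' @export
print.snapshot_set <- function(x, ...) {
  cat(sprintf("snapshot_set: N = %d, Ns = %d (%d params x Nt = %d) [%s]\n",
              nrow(x$S), ncol(x$S), nrow(x$params), x$time$Nt,
              x$scenario_name %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
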