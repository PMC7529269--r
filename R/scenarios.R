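# Benchmark scenario builders: ischemic slab, S1-S2 re-entry induction,
# restitution variability; plus parameter-grid construction.

#' Scenario container
#'
#' Bundles the grid, time discretization, parameter box and the mu-dependent
#' builders for the ionic parameters, conductivity, ionic-current scaling and
#' stimulus protocol.
#'
#' @param name preset name
#' @param grid a `grid2d`
#' @param time a `time_grid`
#' @param ionic_builder function `mu -> ionic_params`
#' @param conductivity_builder function `mu -> conductivity_model`
#' @param stimulus_builder function `mu -> list of stimulus_term`
#' @param reaction_scaling_builder function `mu -> scalar 1 or length-N field`
#'   multiplying the ionic current (default: identically 1)
#' @param param_box 2 x n_mu matrix, rows = (lower, upper)
#' @param train_params,test_params matrices of parameter instances (rows)
#' @param config serializable list (builder name + arguments) for round-trips
#' @return object of class `scenario`
#' @export
scenario <- function(name, grid, time, ionic_builder, conductivity_builder,
                     stimulus_builder, reaction_scaling_builder = NULL,
                     param_box, train_params = NULL, test_params = NULL,
                     config = NULL) {
  if (is.null(reaction_scaling_builder))
    reaction_scaling_builder <- function(mu) 1
  stopifnot(nrow(param_box) == 2, all(param_box[1, ] < param_box[2, ]))
  structure(list(
    name = name, grid = grid, time = time,
    ionic_builder = ionic_builder,
    conductivity_builder = conductivity_builder,
    stimulus_builder = stimulus_builder,
    reaction_scaling_builder = reaction_scaling_builder,
    param_box = param_box,
    train_params = train_params, test_params = test_params,
    config = config
  ), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario '%s': N = %d, n_steps = %d, n_mu = %d, Ntrain = %s, Ntest = %s\n",
              x$name, x$grid$N, x$time$n_steps, ncol(x$param_box),
              if (is.null(x$train_params)) "-" else nrow(x$train_params),
              if (is.null(x$test_params)) "-" else nrow(x$test_params)))
  invisible(x)
}

mu_in_box <- function(mu, box) {
  length(mu) == ncol(box) && all(mu >= box[1, ] - 1e-12) && all(mu <= box[2, ] + 1e-12)
}

#' Smooth ischemic (non-conductive) modulation
#'
#' `rho(x; mu) = 1 - exp(-((x1-mu1)^4 + (x2-mu2)^4) / (2 alpha^2))` vanishes at
#' the scar center `(mu1, mu2)` and tends to 1 in healthy tissue;
#' `sigma = rho + sigma0 (1 - rho)` maps it into `[sigma0, 1]`. `sigma`
#' multiplies the conductivity tensor and `rho` multiplies the ionic current.
#'
#' @param x1,x2 point coordinates (vectorized, cm)
#' @param mu length-2 scar center (cm)
#' @param alpha grey-zone width parameter (cm^2)
#' @param sigma0 residual conductivity fraction at the scar core
#' @return list with fields `rho` and `sigma`
#' @export
ischemic_modulation <- function(x1, x2, mu, alpha = 7, sigma0 = 1e-4) {
  stopifnot(alpha > 0)
  rho <- 1 - exp(-((x1 - mu[1])^4 + (x2 - mu[2])^4) / (2 * alpha^2))
  list(rho = rho, sigma = rho + sigma0 * (1 - rho))
}

#' Axis-aligned lattice of parameter points
#'
#' Point d-th coordinate takes values `box[1,d] + offsets[d] + i * steps[d]`,
#' `i = 0, ..., counts[d]-1`, combined over all axes (first axis fastest).
#'
#' @param box 2 x n_mu box
#' @param counts,offsets,steps per-axis integers / numerics; `steps` defaults
#'   to spanning the remaining box width uniformly
#' @return matrix with `prod(counts)` rows
#' @export
lattice_points <- function(box, counts, offsets = NULL, steps = NULL) {
  d <- ncol(box)
  counts <- unlist(counts); offsets <- unlist(offsets); steps <- unlist(steps)
  if (is.null(offsets)) offsets <- rep(0, d)
  if (is.null(steps))
    steps <- ifelse(counts > 1,
                    (box[2, ] - box[1, ] - 2 * offsets) / pmax(counts - 1, 1), 0)
  axes <- lapply(seq_len(d), function(k)
    box[1, k] + offsets[k] + steps[k] * (seq_len(counts[k]) - 1))
  pts <- as.matrix(expand.grid(axes))
  dimnames(pts) <- list(NULL, paste0("mu", seq_len(d)))
  pts
}

#' Build train/test parameter grids
#'
#' @param box 2 x n_mu parameter box
#' @param spec list describing the points: `type = "lattice"` with
#'   `counts`/`offsets`/`steps`, `type = "uniform"` with `n` and `seed`, or
#'   `type = "midpoints"` with `of` (a matrix of 1D points whose consecutive
#'   midpoints are taken)
#' @return matrix of parameter points (rows), all inside `box`
#' @export
make_parameter_grid <- function(box, spec) {
  pts <- switch(spec$type,
    lattice = lattice_points(box, spec$counts, spec$offsets, spec$steps),
    uniform = {
      stopifnot(!is.null(spec$n), !is.null(spec$seed))
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(spec$seed)
      m <- matrix(stats::runif(spec$n * ncol(box), box[1, ], box[2, ]),
                  nrow = spec$n, byrow = TRUE)
      colnames(m) <- paste0("mu", seq_len(ncol(box)))
      m
    },
    midpoints = {
      of <- as.matrix(spec$of)
      stopifnot(ncol(of) == 1)
      m <- matrix((of[-1, 1] + of[-nrow(of), 1]) / 2, ncol = 1)
      colnames(m) <- "mu1"
      m
    },
    stop("unknown parameter grid type: ", spec$type)
  )
  bad <- which(!apply(pts, 1, mu_in_box, box = box))
  if (length(bad)) stop("parameter points outside the box: rows ", toString(bad))
  pts
}

#' Ischemic-slab benchmark (square slab with a parametrized scar)
#'
#' 10 cm x 10 cm slab; the two parameters are the scar-center coordinates.
#' Defaults: 64 x 64 nodes, dt = 0.1/12.9, T = 400 ms, Nt = 1000 snapshot
#' times, 7 x 7 training lattice (step 0.5 cm) and 6 x 6 testing lattice
#' (offset 0.25 cm), Gaussian stimulus at the origin (C = 100, beta = 0.02
#' cm^2, 2 ms), conductivities sigma_l = 12.9*0.2, sigma_t = 12.9*0.1 cm^2/ms,
#' fibers along x.
#'
#' @param nx,ny node counts
#' @param dt time step (rescaled)
#' @param T_ms final time (ms)
#' @param Nt snapshot count
#' @param train,test parameter-grid specs (see [make_parameter_grid()])
#' @param alpha,sigma0 modulation parameters of [ischemic_modulation()]
#' @return a `scenario`
#' @export
build_test1 <- function(nx = 64, ny = nx, dt = 0.1 / 12.9, T_ms = 400,
                        Nt = 1000,
                        train = list(type = "lattice", counts = c(7, 7),
                                     offsets = c(0, 0), steps = c(0.5, 0.5)),
                        test = list(type = "lattice", counts = c(6, 6),
                                    offsets = c(0.25, 0.25), steps = c(0.5, 0.5)),
                        alpha = 7, sigma0 = 1e-4) {
  cfg <- list(builder = "test1",
              args = list(nx = nx, ny = ny, dt = dt, T_ms = T_ms, Nt = Nt,
                          train = train, test = test,
                          alpha = alpha, sigma0 = sigma0))
  g <- grid2d(nx, ny, 10, 10)
  tg <- time_grid(dt, T_ms, Nt)
  box <- rbind(c(3.5, 3.5), c(6.5, 6.5))
  ion <- ionic_params(K = 8, a = 0.01, b = 0.15, eps0 = 0.002, c1 = 0.2, c2 = 0.3)
  sl <- 12.9 * 0.2; st <- 12.9 * 0.1
  scenario(
    name = "test1", grid = g, time = tg,
    ionic_builder = function(mu) ion,
    conductivity_builder = function(mu) {
      m <- ischemic_modulation(g$x, g$y, mu, alpha, sigma0)
      conductivity_model(sl, st, f0 = c(1, 0), modulation = m$sigma)
    },
    reaction_scaling_builder = function(mu)
      ischemic_modulation(g$x, g$y, mu, alpha, sigma0)$rho,
    stimulus_builder = function(mu)
      list(gaussian_stimulus(C = 100, beta_cm2 = 0.02, center = c(0, 0),
                             t_on_ms = 0, t_off_ms = 2)),
    param_box = box,
    train_params = make_parameter_grid(box, train),
    test_params = make_parameter_grid(box, test),
    config = cfg
  )
}

#' Desk-scale variant of the ischemic-slab benchmark
#'
#' 32 x 32 nodes, Nt = 200, 3 x 3 training lattice and 2 x 2 testing lattice.
#' @param ... overrides forwarded to [build_test1()]
#' @export
build_test1_mini <- function(...) {
  args <- utils::modifyList(list(
    nx = 32, Nt = 200,
    train = list(type = "lattice", counts = c(3, 3),
                 offsets = c(0, 0), steps = c(1.5, 1.5)),
    test = list(type = "lattice", counts = c(2, 2),
                offsets = c(0.75, 0.75), steps = c(1.5, 1.5))
  ), list(...))
  sc <- do.call(build_test1, args)
  sc$name <- "test1-mini"
  sc$config$builder <- "test1-mini"
  sc
}

#' S1-S2 re-entry benchmark (figure-of-eight re-entry on a 2 cm slab)
#'
#' S1 activates the bottom strip `y <= 0.1` over [0, 5] ms; S2 is a disk of
#' radius 0.2 cm centered at `(1, mu)` active over [70, 75] ms. Snapshots are
#' collected only over [95, 175] ms (the window over which re-entry has
#' developed). The single parameter is the y-coordinate of the S2 center.
#'
#' @param variant `"full"` (parameter box [0.5, 1.1] cm: re-entry and
#'   non-re-entry) or `"reentry_only"` ([0.8, 1.1] cm)
#' @param nx,ny node counts (default 256)
#' @param dt time step (rescaled)
#' @param Nt snapshot count over the window
#' @param n_train training instances (uniformly spaced, endpoints included);
#'   testing instances are the midpoints of consecutive training points
#' @return a `scenario`
#' @export
build_test2 <- function(variant = c("full", "reentry_only"),
                        nx = 256, ny = nx, dt = 0.2 / 12.9, Nt = 400,
                        n_train = 13) {
  variant <- match.arg(variant)
  cfg <- list(builder = "test2",
              args = list(variant = variant, nx = nx, ny = ny, dt = dt,
                          Nt = Nt, n_train = n_train))
  g <- grid2d(nx, ny, 2, 2)
  tg <- time_grid(dt, T_ms = 175, Nt = Nt, window_ms = c(95, 175))
  box <- if (variant == "full") rbind(0.5, 1.1) else rbind(0.8, 1.1)
  ion <- ionic_params(K = 8, a = 0.1, b = 0.1, eps0 = 0.01, c1 = 0.14, c2 = 0.3)
  train <- matrix(seq(box[1], box[2], length.out = n_train), ncol = 1,
                  dimnames = list(NULL, "mu1"))
  scenario(
    name = paste0("test2-", variant), grid = g, time = tg,
    ionic_builder = function(mu) ion,
    conductivity_builder = function(mu)
      conductivity_model(2e-3, 3.1e-4, f0 = c(1, 0)),
    stimulus_builder = function(mu) list(
      indicator_stimulus(function(x, y) y <= 0.1, amplitude = 1,
                         t_on_ms = 0, t_off_ms = 5, label = "S1"),
      indicator_stimulus(function(x, y) (x - 1)^2 + (y - mu[1])^2 <= 0.2^2,
                         amplitude = 1, t_on_ms = 70, t_off_ms = 75,
                         label = "S2")
    ),
    param_box = box,
    train_params = train,
    test_params = make_parameter_grid(box, list(type = "midpoints", of = train)),
    config = cfg
  )
}

#' Restitution-variability benchmark (conductivities + APD parameter)
#'
#' 10 cm x 10 cm slab, stimulus as in the ischemic-slab benchmark but without
#' a scar; `mu1`/`mu2` are the longitudinal/transversal conductivities
#' (`D = mu2 I + (mu1 - mu2) f0 f0^T`) and `mu3` replaces `c1` in the gating
#' dynamics, regulating the action potential duration. Training lattice
#' 5 x 5 x 5; the printed testing lattice is 4 x 4 x 4 but only `n_test`
#' points (default 16, lexicographic order) are used.
#'
#' @inheritParams build_test1
#' @param n_test number of testing instances retained from the testing lattice
#' @return a `scenario`
#' @export
build_test4 <- function(nx = 64, ny = nx, dt = 0.1 / 12.9, T_ms = 400,
                        Nt = 1000, n_test = 16) {
  cfg <- list(builder = "test4",
              args = list(nx = nx, ny = ny, dt = dt, T_ms = T_ms, Nt = Nt,
                          n_test = n_test))
  g <- grid2d(nx, ny, 10, 10)
  tg <- time_grid(dt, T_ms, Nt)
  box <- rbind(c(12.9 * 0.06, 12.9 * 0.03, 0.15),
               c(12.9 * 0.2, 12.9 * 0.1, 0.25))
  train <- lattice_points(box, counts = c(5, 5, 5), offsets = c(0, 0, 0),
                          steps = c(12.9 * 0.035, 12.9 * 0.0175, 0.025))
  test_all <- lattice_points(
    rbind(c(12.9 * 0.0775, 12.9 * 0.0387, 0.1625), box[2, ]),
    counts = c(4, 4, 4),
    steps = c(12.9 * 0.035, 12.9 * 0.0175, 0.025))
  scenario(
    name = "test4", grid = g, time = tg,
    ionic_builder = function(mu)
      ionic_params(K = 8, a = 0.01, b = 0.15, eps0 = 0.002, c1 = mu[3], c2 = 0.3),
    conductivity_builder = function(mu)
      conductivity_model(mu[1], mu[2], f0 = c(1, 0), strict = FALSE),
    stimulus_builder = function(mu)
      list(gaussian_stimulus(C = 100, beta_cm2 = 0.02, center = c(0, 0),
                             t_on_ms = 0, t_off_ms = 2)),
    param_box = box,
    train_params = train,
    test_params = test_all[seq_len(n_test), , drop = FALSE],
    config = cfg
  )
}

SCENARIO_BUILDERS <- list(
  "test1" = "build_test1",
  "test1-mini" = "build_test1_mini",
  "test2" = "build_test2",
  "test4" = "build_test4"
)

#' Serialize a scenario to a config list / rebuild it
#'
#' The config records the builder name and its arguments, so
#' `scenario_from_config(scenario_to_config(sc))` reproduces `sc` and the
#' round-trip config is lossless.
#'
#' @param sc a `scenario`
#' @return a plain list suitable for `yaml::write_yaml`
#' @export
scenario_to_config <- function(sc) {
  if (is.null(sc$config)) stop("scenario has no serializable config")
  sc$config
}

#' @rdname scenario_to_config
#' @param cfg config list with `builder` and `args`
#' @export
scenario_from_config <- function(cfg) {
  fname <- SCENARIO_BUILDERS[[cfg$builder]]
  if (is.null(fname))
    stop("unknown scenario '", cfg$builder, "'; valid presets: ",
         toString(names(SCENARIO_BUILDERS)))
  args <- cfg$args %||% list()
  # YAML deserializes matrices as lists; restore midpoint specs if present
  do.call(get(fname, envir = asNamespace("cardioROM")), args)
}

#' Load a scenario preset (packaged YAML or user file)
#' @param name preset name (e.g. `"test1-mini"`) or path to a YAML config
#' @export
load_scenario <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "scenarios", paste0(name, ".yaml"),
                package = "cardioROM")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown scenario '", name, "'; valid presets: ",
         toString(names(SCENARIO_BUILDERS)))
  scenario_from_config(yaml::read_yaml(path))
}
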