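# DL-ROM: convolutional autoencoder + deep feedforward network learning the
# nonlinear trial manifold and the reduced dynamics. The trained model is
# queried as u(t; mu) ~ decoder(dfnn(t, mu)) -- no time stepping, no encoder.

#' DL-ROM network architecture
#'
#' Encoder: `length(conv_channels)` convolutional layers (kernel x kernel,
#' given stride, zero padding, ELU) followed by a linear dense layer to the
#' latent dimension `n`. Decoder: mirror image (dense + ELU, then transposed
#' convolutions, last layer linear). DFNN: `dfnn_hidden` ELU layers from the
#' `n_mu + 1` inputs `(t, mu)` to `n`.
#'
#' @param n latent (ROM) dimension
#' @param n_mu number of scenario parameters
#' @param image_side side `s` of the square input images (`s^2 >= N`)
#' @param conv_channels channel counts per conv level
#' @param kernel odd kernel size
#' @param stride conv stride (each level divides the side by this, rounding up)
#' @param dfnn_hidden hidden-layer widths of the DFNN
#' @return object of class `dlrom_architecture`
#' @export
dlrom_architecture <- function(n, n_mu, image_side,
                               conv_channels = c(8, 16, 32, 64),
                               kernel = 5, stride = 2,
                               dfnn_hidden = rep(50L, 4)) {
  stopifnot(n >= 1, n_mu >= 1, image_side >= 2,
            kernel %% 2 == 1, stride >= 1, length(conv_channels) >= 1)
  side <- image_side
  pad <- (kernel - 1) / 2
  for (l in seq_along(conv_channels)) {
    side <- floor((side + 2 * pad - kernel) / stride) + 1
    if (side < 1) stop("conv stack collapses the image; fewer layers needed")
  }
  structure(list(n = as.integer(n), n_mu = as.integer(n_mu),
                 image_side = as.integer(image_side),
                 conv_channels = as.integer(conv_channels),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 dfnn_hidden = as.integer(dfnn_hidden),
                 top_side = as.integer(side)),
            class = "dlrom_architecture")
}

#' Training configuration
#'
#' @param learning_rate ADAM starting learning rate
#' @param batch_size minibatch size
#' @param max_epochs epoch budget
#' @param patience early stopping: abort when the validation loss has not
#'   reached a new strict minimum within this many epochs
#' @param omega_h reconstruction-vs-code loss weight in `[0, 1]`
#' @param val_fraction validation share of the samples (random, per-sample)
#' @param seed single manifest seed for split, init and batching
#' @return object of class `dlrom_train_config`
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 40,
                         max_epochs = 10000, patience = 500,
                         omega_h = 0.5, val_fraction = 0.2, seed = 1) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, patience <= max_epochs,
            omega_h >= 0, omega_h <= 1, val_fraction > 0, val_fraction < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 omega_h = omega_h, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "dlrom_train_config")
}

#' Tensorize a snapshot set for DL-ROM training
#'
#' Each snapshot column is min-max scaled to `[0, 1]` with global training
#' statistics and zero-padded from length N to the smallest enclosing square
#' `s^2`, `s = ceil(sqrt(N))`; padded cells are masked out of the
#' reconstruction loss. The inputs `(t, mu)` are min-max scaled per component.
#'
#' @param snaps a `snapshot_set` (or any list with `S` and a `labels`
#'   data.frame containing `t` and `mu*` columns)
#' @return object of class `dlrom_dataset`
#' @export
prepare_dataset <- function(snaps) {
  S <- snaps$S
  stopifnot(is.matrix(S), all(is.finite(S)))
  N <- nrow(S)
  s <- ceiling(sqrt(N))
  u_min <- min(S); u_max <- max(S)
  if (u_max <= u_min) stop("constant snapshot matrix (max = min)")
  U <- (S - u_min) / (u_max - u_min)
  if (s^2 > N) U <- rbind(U, matrix(0, s^2 - N, ncol(S)))
  mask <- c(rep(1, N), rep(0, s^2 - N))

  mu_cols <- grep("^mu", names(snaps$labels), value = TRUE)
  X_raw <- t(as.matrix(snaps$labels[, c("t", mu_cols), drop = FALSE]))
  x_min <- apply(X_raw, 1, min); x_max <- apply(X_raw, 1, max)
  if (any(x_max <= x_min)) stop("constant (t, mu) input component")
  X <- (X_raw - x_min) / (x_max - x_min)

  structure(list(U = U, X = X, mask = mask, s = as.integer(s), N = N,
                 n_mu = length(mu_cols),
                 norm = list(u_min = u_min, u_max = u_max,
                             x_min = x_min, x_max = x_max),
                 labels = snaps$labels),
            class = "dlrom_dataset")
}

#' Per-example DL-ROM loss
#'
#' `L = omega_h/2 ||u - u_rec||^2 + (1 - omega_h)/2 ||code_enc - code_dfnn||^2`
#' averaged over the examples (columns).
#'
#' @param u,u_rec truth and reconstruction (matching matrices, columns =
#'   examples)
#' @param code_enc,code_dfnn encoder output and intrinsic coordinates
#' @param omega_h weight in `[0, 1]`
#' @return scalar mean loss
#' @export
dlrom_loss <- function(u, u_rec, code_enc, code_dfnn, omega_h) {
  u <- as.matrix(u); u_rec <- as.matrix(u_rec)
  code_enc <- as.matrix(code_enc); code_dfnn <- as.matrix(code_dfnn)
  stopifnot(all(dim(u) == dim(u_rec)), all(dim(code_enc) == dim(code_dfnn)))
  rec <- colSums((u - u_rec)^2)
  code <- colSums((code_enc - code_dfnn)^2)
  mean(omega_h / 2 * rec + (1 - omega_h) / 2 * code)
}

#' Train a DL-ROM
#'
#' Minimizes the mean per-example loss over all `Ns` samples with ADAM, using
#' a random, seeded 8:2 train/validation split of individual `(t, mu)` samples
#' and early stopping on the validation loss; returns the weights of the best
#' validation checkpoint. Fully reproducible for a fixed seed.
#'
#' @param dataset a `dlrom_dataset`
#' @param arch a `dlrom_architecture` (its `image_side` must equal the
#'   dataset's)
#' @param config a `dlrom_train_config`
#' @return object of class `trained_dlrom` with the architecture, weights,
#'   normalization statistics, padding metadata and per-epoch history
#' @export
train_dlrom <- function(dataset, arch, config = train_config()) {
  stopifnot(inherits(dataset, "dlrom_dataset"),
            inherits(arch, "dlrom_architecture"))
  if (arch$image_side != dataset$s)
    stop("architecture image_side != dataset image side")
  if (arch$n_mu != dataset$n_mu)
    stop("architecture n_mu != dataset parameter count")
  fit <- .dlrom_train_cpp(dataset$U, dataset$X, dataset$mask,
                          unclass(arch), unclass(config))
  history <- data.frame(epoch = seq_along(fit$train_loss),
                        train_loss = fit$train_loss,
                        val_loss = fit$val_loss)
  structure(list(arch = arch, config = config, weights = fit$weights,
                 norm = dataset$norm, mask = dataset$mask,
                 s = dataset$s, N = dataset$N,
                 history = history,
                 val_idx = as.integer(fit$val_idx),
                 best_epoch = fit$best_epoch,
                 best_val_loss = fit$best_val_loss,
                 seed = config$seed),
            class = "trained_dlrom")
}

#' @export
print.trained_dlrom <- function(x, ...) {
  cat(sprintf("trained_dlrom: n = %d, N = %d (side %d), %d epochs, best val loss %.3e (epoch %d)\n",
              x$arch$n, x$N, x$s, nrow(x$history), x$best_val_loss, x$best_epoch))
  invisible(x)
}

scale_inputs <- function(model, t, mu) {
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = length(t),
                                     ncol = model$arch$n_mu, byrow = TRUE)
  stopifnot(nrow(mu) == length(t), ncol(mu) == model$arch$n_mu)
  X_raw <- rbind(t, t(mu))
  X <- (X_raw - model$norm$x_min) / (model$norm$x_max - model$norm$x_min)
  if (any(X < -1e-9) || any(X > 1 + 1e-9))
    warning("query (t, mu) outside the training range; extrapolating")
  X
}

#' Evaluate the DL-ROM at (t, mu)
#'
#' Evaluates the DFNN and the decoder only -- no encoder, no time stepping:
#' any time instant can be queried directly, in any order, statelessly.
#'
#' @param model a `trained_dlrom`
#' @param t vector of rescaled query times
#' @param mu single parameter vector (recycled over `t`) or a matrix with one
#'   row per query
#' @return N x length(t) matrix of dimensionless potentials
#' @export
predict_dlrom <- function(model, t, mu) {
  X <- scale_inputs(model, t, mu)
  rec <- .dlrom_predict_cpp(unclass(model$arch), model$weights, X)
  u <- rec[seq_len(model$N), , drop = FALSE]
  u * (model$norm$u_max - model$norm$u_min) + model$norm$u_min
}

#' Latent intrinsic coordinates of the DL-ROM at (t, mu)
#' @inheritParams predict_dlrom
#' @return n x length(t) matrix of latent codes
#' @export
latent_coordinates <- function(model, t, mu) {
  X <- scale_inputs(model, t, mu)
  .dlrom_dfnn_cpp(unclass(model$arch), model$weights, X)
}

#' Encode full-order states to latent codes (diagnostics)
#' @param model a `trained_dlrom`
#' @param u length-N vector or N x M matrix of dimensionless potentials
#' @return n x M matrix of codes
#' @export
encode_dlrom <- function(model, u) {
  u <- as.matrix(u)
  stopifnot(nrow(u) == model$N)
  U <- (u - model$norm$u_min) / (model$norm$u_max - model$norm$u_min)
  if (model$s^2 > model$N)
    U <- rbind(U, matrix(0, model$s^2 - model$N, ncol(U)))
  .dlrom_encode_cpp(unclass(model$arch), model$weights, U)
}

#' Predict a whole trajectory for one parameter instance
#' @param model a `trained_dlrom`
#' @param times rescaled sample times
#' @param mu parameter vector
#' @return N x length(times) matrix
#' @export
predict_trajectory <- function(model, times, mu) {
  predict_dlrom(model, times, matrix(mu, nrow = length(times),
                                     ncol = length(mu), byrow = TRUE))
}

#' Save / load a trained DL-ROM
#'
#' A model directory holds the weights blob (`weights.rds`), the architecture,
#' config and normalization as JSON, and the training history as CSV.
#'
#' @param model a `trained_dlrom`
#' @param dir target directory (created)
#' @export
save_dlrom <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model$weights, file.path(dir, "weights.rds"))
  meta <- list(arch = unclass(model$arch), config = unclass(model$config),
               norm = model$norm, s = model$s, N = model$N,
               best_epoch = model$best_epoch,
               best_val_loss = model$best_val_loss, seed = model$seed)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(model$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname save_dlrom
#' @export
load_dlrom <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  arch <- do.call(dlrom_architecture,
                  meta$arch[c("n", "n_mu", "image_side", "conv_channels",
                              "kernel", "stride", "dfnn_hidden")])
  cfg <- do.call(train_config, meta$config)
  weights <- readRDS(file.path(dir, "weights.rds"))
  history <- utils::read.csv(file.path(dir, "history.csv"))
  structure(list(arch = arch, config = cfg, weights = weights,
                 norm = list(u_min = meta$norm$u_min, u_max = meta$norm$u_max,
                             x_min = meta$norm$x_min, x_max = meta$norm$x_max),
                 s = meta$s, N = meta$N, history = history,
                 best_epoch = meta$best_epoch,
                 best_val_loss = meta$best_val_loss, seed = meta$seed),
            class = "trained_dlrom")
}

#' Synthetic rank-one manifold snapshots (desk benchmark)
#'
#' `u(t; mu) = sin(pi t) * mu * phi(x)` on an `n_side x n_side` grid with a
#' fixed smooth spatial profile `phi`: the solution set is an exactly
#' two-parameter manifold, so a latent dimension of 2 suffices. Used as a
#' recovery benchmark for the DL-ROM training loop.
#'
#' @param n_side image side (default 16)
#' @param Nt time samples on `[0, 1]`
#' @param mu_values parameter values (one trajectory per value)
#' @return a `snapshot_set`-shaped list consumable by [prepare_dataset()]
#' @export
toy_manifold_snapshots <- function(n_side = 16, Nt = 50,
                                   mu_values = seq(1, 2, length.out = 8)) {
  g <- grid2d(n_side, n_side, 1, 1)
  phi <- exp(-((g$x - 0.35)^2 + (g$y - 0.6)^2) / 0.05) +
    0.5 * sin(2 * pi * g$x) * cos(pi * g$y)
  ts <- seq(0, 1, length.out = Nt)
  S <- do.call(cbind, lapply(mu_values, function(m) outer(phi, sin(pi * ts) * m)))
  labels <- data.frame(t = rep(ts, times = length(mu_values)),
                       param_id = rep(seq_along(mu_values), each = Nt),
                       mu1 = rep(mu_values, each = Nt))
  structure(list(S = S, F = NULL, W = NULL, labels = labels,
                 params = matrix(mu_values, ncol = 1,
                                 dimnames = list(NULL, "mu1")),
                 scenario_name = "toy-manifold", grid = g,
                 time = list(Nt = Nt)),
            class = "snapshot_set")
}
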