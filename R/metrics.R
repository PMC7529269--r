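# Error indicators and clinical outputs (activation maps, APD).

#' Time-averaged relative error indicator
#'
#' For each test instance i:
#' `sqrt( sum_k ||u^k - u~^k||^2 / sum_k ||u^k||^2 )` (Euclidean norms over
#' space, sums over the sampled times), averaged over the test instances.
#'
#' @param U_true,U_pred lists of N x Nt matrices (one per test instance), or a
#'   single matrix each
#' @return scalar error indicator (>= 0; 0 iff prediction equals truth)
#' @export
eps_rel <- function(U_true, U_pred) {
  if (is.matrix(U_true)) U_true <- list(U_true)
  if (is.matrix(U_pred)) U_pred <- list(U_pred)
  stopifnot(length(U_true) == length(U_pred))
  vals <- mapply(function(u, up) {
    stopifnot(all(dim(u) == dim(up)))
    den <- sum(u^2)
    if (den == 0) stop("eps_rel: zero-norm truth trajectory")
    sqrt(sum((u - up)^2) / den)
  }, U_true, U_pred)
  mean(vals)
}

#' Per-node relative error field at one time
#'
#' `|u^k - u~^k| / ((1/Nt) sum_k ||u^k||_2)`: elementwise absolute error
#' normalized by the time-mean of the truth's spatial 2-norms.
#'
#' @param u_k,u_pred_k length-N truth and prediction at time k
#' @param U_true N x Nt truth trajectory supplying the normalization
#' @return length-N nonnegative field
#' @export
eps_k <- function(u_k, u_pred_k, U_true) {
  den <- mean(sqrt(colSums(U_true^2)))
  if (den <= 0) stop("eps_k: zero normalization")
  abs(u_k - u_pred_k) / den
}

#' Per-node percent error field at one time
#'
#' `|u^k - u~^k| / ||u^k||_1 * 100` (1-norm normalization as a percentage).
#'
#' @param u_k,u_pred_k length-N truth and prediction at time k
#' @return length-N field in percent
#' @export
eps_ks <- function(u_k, u_pred_k) {
  den <- sum(abs(u_k))
  if (den <= 0) stop("eps_ks: zero 1-norm")
  abs(u_k - u_pred_k) / den * 100
}

#' Activation map
#'
#' Activation time of a node is the first upward crossing of the threshold,
#' linearly interpolated between consecutive samples and reported in ms.
#' Nodes that never cross get `NA`.
#'
#' @param U N x Nt trajectory (dimensionless potential)
#' @param times rescaled sample times (length Nt, increasing)
#' @param threshold dimensionless threshold (default 0.5, about -30 mV)
#' @return object of class `activation_map`: `t_act_ms` (length N, NA =
#'   unactivated) and the threshold used
#' @export
activation_map <- function(U, times, threshold = 0.5) {
  stopifnot(ncol(U) == length(times), ncol(U) >= 1, !is.unsorted(times))
  N <- nrow(U); Nt <- ncol(U)
  t_ms <- TIME_SCALE_MS * times
  t_act <- rep(NA_real_, N)
  above <- U >= threshold
  done <- rep(FALSE, N)
  # initial sample already above: activation at the first sample time
  first <- above[, 1]
  t_act[first] <- t_ms[1]
  done <- first
  for (k in seq_len(Nt - 1)) {
    cross <- !done & !above[, k] & above[, k + 1]
    if (any(cross)) {
      u0 <- U[cross, k]; u1 <- U[cross, k + 1]
      frac <- (threshold - u0) / (u1 - u0)
      t_act[cross] <- t_ms[k] + frac * (t_ms[k + 1] - t_ms[k])
      done[cross] <- TRUE
    }
    if (all(done)) break
  }
  structure(list(t_act_ms = t_act, threshold = threshold),
            class = "activation_map")
}

#' Action potential duration map
#'
#' Total dimensional time each node spends above the threshold (trapezoidal
#' accounting with linear interpolation at partial crossings).
#'
#' @inheritParams activation_map
#' @return length-N APD vector in ms (0 for nodes never above threshold)
#' @export
apd_map <- function(U, times, threshold = 0.5) {
  stopifnot(ncol(U) == length(times), !is.unsorted(times))
  N <- nrow(U); Nt <- ncol(U)
  t_ms <- TIME_SCALE_MS * times
  apd <- numeric(N)
  if (Nt == 1) return(apd)
  above <- U >= threshold
  for (k in seq_len(Nt - 1)) {
    dtk <- t_ms[k + 1] - t_ms[k]
    a0 <- above[, k]; a1 <- above[, k + 1]
    both <- a0 & a1
    apd[both] <- apd[both] + dtk
    mixed <- xor(a0, a1)
    if (any(mixed)) {
      u0 <- U[mixed, k]; u1 <- U[mixed, k + 1]
      frac <- abs((threshold - u0) / (u1 - u0))
      # fraction of the interval spent above the threshold
      fr_above <- ifelse(a0[mixed], frac, 1 - frac)
      apd[mixed] <- apd[mixed] + fr_above * dtk
    }
  }
  apd
}

#' Error report over a test set
#'
#' @param U_true,U_pred lists of trajectories (see [eps_rel()])
#' @param model_id optional identifier stored in the report
#' @return list with `eps_rel` and metadata; serializable to JSON
#' @export
error_report <- function(U_true, U_pred, model_id = NULL) {
  list(model_id = model_id,
       n_test = if (is.matrix(U_true)) 1L else length(U_true),
       eps_rel = eps_rel(U_true, U_pred))
}
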