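# Linear projection-based ROM: POD bases (global or local), DEIM
# hyper-reduction, and the reduced semi-implicit online solver.

#' POD basis from a snapshot matrix
#'
#' Thin SVD of the snapshots; the retained dimension is the smallest `n` such
#' that `sum_{i<=n} s_i^2 / sum_i s_i^2 > 1 - eps_pod^2` (strict inequality),
#' unless `n_fixed` is given. The sign of each mode is fixed so that its first
#' nonzero entry is positive (reproducibility).
#'
#' @param S N x Ns snapshot matrix
#' @param eps_pod energy tolerance in (0, 1)
#' @param n_fixed retain exactly this many modes instead
#' @return object of class `pod_basis`: `V` (N x n, orthonormal),
#'   `singular_values` (full spectrum), `n`, `eps_pod`
#' @export
pod_basis <- function(S, eps_pod = NULL, n_fixed = NULL) {
  stopifnot(is.matrix(S), ncol(S) >= 1)
  sv <- svd(S, nu = min(dim(S)), nv = 0)
  s2 <- sv$d^2
  if (!is.null(n_fixed)) {
    n <- min(as.integer(n_fixed), sum(sv$d > sv$d[1] * 1e-14))
  } else {
    if (is.null(eps_pod) || eps_pod <= 0 || eps_pod >= 1)
      stop("eps_pod must lie in (0, 1)")
    energy <- cumsum(s2) / sum(s2)
    n <- which(energy > 1 - eps_pod^2)[1]
  }
  V <- sv$u[, seq_len(n), drop = FALSE]
  # sign convention: first nonzero entry of each mode positive
  for (j in seq_len(n)) {
    nz <- which(abs(V[, j]) > 1e-12)[1]
    if (!is.na(nz) && V[nz, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(V = V, singular_values = sv$d, n = n, eps_pod = eps_pod),
            class = "pod_basis")
}

#' k-means clustering of snapshot columns (k-means++ seeding)
#'
#' @param S N x Ns snapshot matrix (columns are clustered in state space)
#' @param Nc number of clusters (1 returns the trivial clustering)
#' @param seed RNG seed (deterministic labels for a fixed seed)
#' @param retries re-seeding budget if a cluster comes back empty
#' @return list with `labels` (length Ns) and `centroids` (Nc x N)
#' @export
cluster_snapshots <- function(S, Nc, seed = 1, retries = 5) {
  Ns <- ncol(S)
  stopifnot(Nc >= 1, Nc <= Ns)
  if (Nc == 1)
    return(list(labels = rep(1L, Ns),
                centroids = matrix(rowMeans(S), nrow = 1)))
  X <- t(S)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (attempt in seq_len(retries)) {
    set.seed(seed + attempt - 1L)
    centers <- kmeanspp_init(X, Nc)
    km <- suppressWarnings(
      stats::kmeans(X, centers = centers, iter.max = 100, algorithm = "Lloyd"))
    if (all(tabulate(km$cluster, Nc) > 0))
      return(list(labels = km$cluster, centroids = km$centers))
  }
  stop("cluster_snapshots: empty cluster after ", retries, " re-seedings")
}

# k-means++ seeding (squared-distance sampling)
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    p <- d2 / sum(d2)
    idx <- sample.int(n, 1, prob = p)
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2))
  }
  centers
}

#' Discrete empirical interpolation (DEIM) of the nonlinear term
#'
#' POD of the nonlinear-term snapshots gives the basis `Phi`; the standard
#' greedy selection picks `m` distinct interpolation nodes. The resulting
#' interpolant of a vector `f` is `Phi (P^T Phi)^{-1} P^T f`, exact on
#' `span(Phi)`.
#'
#' @param F_snapshots N x Ns matrix of nonlinear-term snapshots
#' @param m fixed number of modes / nodes
#' @param eps_deim energy tolerance used instead of `m`
#' @return object of class `deim_model`: `Phi` (N x m), `indices` (m distinct
#'   node indices), `PtPhi_inv` and an `interpolate(f)` closure
#' @export
deim <- function(F_snapshots, m = NULL, eps_deim = NULL) {
  pb <- pod_basis(F_snapshots, eps_pod = eps_deim, n_fixed = m)
  Phi <- pb$V
  m <- pb$n
  indices <- integer(m)
  indices[1] <- which.max(abs(Phi[, 1]))
  if (m > 1) {
    for (l in 2:m) {
      U <- Phi[, seq_len(l - 1), drop = FALSE]
      c_l <- solve(U[indices[seq_len(l - 1)], , drop = FALSE],
                   Phi[indices[seq_len(l - 1)], l])
      r <- Phi[, l] - U %*% c_l
      r[indices[seq_len(l - 1)]] <- 0
      indices[l] <- which.max(abs(r))
    }
  }
  PtPhi <- Phi[indices, , drop = FALSE]
  if (abs(det(PtPhi)) < 1e-300) stop("deim: singular (P^T Phi)")
  PtPhi_inv <- solve(PtPhi)
  structure(list(
    Phi = Phi, indices = indices, m = m, PtPhi_inv = PtPhi_inv,
    interpolate = function(f) as.numeric(Phi %*% (PtPhi_inv %*% f[indices]))
  ), class = "deim_model")
}

#' Build a (local) POD-Galerkin + DEIM model from a snapshot set
#'
#' Snapshot columns are optionally split into `Nc` clusters (k-means in state
#' space); each cluster gets its own POD basis for the potential and its own
#' DEIM space for the recorded nonlinear-term snapshots.
#'
#' @param snaps a `snapshot_set`
#' @param eps_pod POD energy tolerance (or `n_fixed`)
#' @param n_fixed fixed POD dimension per cluster
#' @param eps_deim DEIM energy tolerance (defaults to `eps_pod`)
#' @param m_fixed fixed DEIM dimension per cluster
#' @param Nc number of local bases
#' @param seed clustering seed
#' @return object of class `pod_local_model`
#' @export
build_pod_rom <- function(snaps, eps_pod = 1e-3, n_fixed = NULL,
                          eps_deim = NULL, m_fixed = NULL, Nc = 1, seed = 1) {
  stopifnot(inherits(snaps, "snapshot_set"))
  if (is.null(eps_deim) && is.null(m_fixed)) eps_deim <- eps_pod
  cl <- cluster_snapshots(snaps$S, Nc, seed = seed)
  clusters <- lapply(seq_len(Nc), function(c) {
    cols <- which(cl$labels == c)
    basis <- pod_basis(snaps$S[, cols, drop = FALSE],
                       eps_pod = eps_pod, n_fixed = n_fixed)
    dm <- deim(snaps$F[, cols, drop = FALSE], m = m_fixed, eps_deim = eps_deim)
    list(basis = basis, deim = dm, n = basis$n, m = dm$m)
  })
  structure(list(clusters = clusters, centroids = cl$centroids,
                 labels = cl$labels, Nc = Nc,
                 scenario_name = snaps$scenario_name,
                 eps_pod = eps_pod, eps_deim = eps_deim, seed = seed),
            class = "pod_local_model")
}

#' @export
print.pod_local_model <- function(x, ...) {
  ns <- vapply(x$clusters, `[[`, integer(1) + 0, "n")
  ms <- vapply(x$clusters, `[[`, integer(1) + 0, "m")
  cat(sprintf("pod_local_model: Nc = %d, n = {%s}, m = {%s}\n",
              x$Nc, toString(ns), toString(ms)))
  invisible(x)
}

#' Solve the reduced (POD-Galerkin + DEIM) system online
#'
#' Time-marches the projected dynamics with the same semi-implicit scheme as
#' the full-order solver; the ionic term is evaluated only at the active
#' cluster's DEIM nodes and the gating variable is advanced only there. The
#' active local basis is chosen each step as the nearest centroid to the
#' reconstructed state (computed without touching N-sized arrays, via
#' precomputed centroid projections). On a basis switch, the reduced
#' coordinates are mapped through the basis cross-Gramian and gating values at
#' nodes not shared with the previous cluster are taken from the lazily
#' maintained gating store.
#'
#' @param model a `pod_local_model`
#' @param sc the `scenario` the snapshots came from
#' @param mu online parameter instance
#' @param tg optional `time_grid` override
#' @param check_box reject `mu` outside the box
#' @return object of class `rom_trajectory`: reduced coordinates per sample,
#'   active cluster ids, sample times, and `U` (reconstructed N x Nt matrix)
#' @export
solve_pod_rom <- function(model, sc, mu, tg = NULL, check_box = TRUE) {
  if (is.null(tg)) tg <- sc$time
  mu <- as.numeric(mu)
  if (check_box && !mu_in_box(mu, sc$param_box))
    stop("mu outside the scenario parameter box")

  grid <- sc$grid
  ionic <- sc$ionic_builder(mu)
  cond <- sc$conductivity_builder(mu)
  rho <- sc$reaction_scaling_builder(mu)
  if (length(rho) == 1) rho <- rep(rho, grid$N)
  stims <- sc$stimulus_builder(mu)
  ops <- assemble_operators(grid, cond)
  mass <- ops$mass; A <- ops$stiffness
  dt <- tg$dt

  # per-cluster offline/μ-dependent operators
  pre <- lapply(model$clusters, function(clu) {
    V <- clu$basis$V
    MV <- V * mass                       # M V (lumped mass)
    Mr <- crossprod(V, MV)
    Ar <- as.matrix(Matrix::crossprod(V, A %*% V))
    sys <- Mr / dt + Ar
    idx <- clu$deim$indices
    list(
      V = V, n = clu$n, idx = idx,
      sys_chol = chol((sys + t(sys)) / 2),
      Mr = Mr,
      E = crossprod(MV, clu$deim$Phi) %*% clu$deim$PtPhi_inv,  # V^T M Phi (P^T Phi)^{-1}
      PtV = V[idx, , drop = FALSE],
      rho_P = rho[idx],
      stim_red = lapply(stims, function(s)
        list(r = as.numeric(crossprod(MV, s$profile(grid$x, grid$y))),
             win = c(s$t_on_ms, s$t_off_ms))),
      CtV = model$centroids %*% V,       # Nc x n
      cnorm2 = rowSums(model$centroids^2)
    )
  })
  # basis cross-Gramians for coordinate transfer on cluster switch
  cross <- NULL
  if (model$Nc > 1)
    cross <- lapply(seq_len(model$Nc), function(a)
      lapply(seq_len(model$Nc), function(b)
        crossprod(pre[[a]]$V, pre[[b]]$V)))

  active <- 1L
  if (model$Nc > 1) {
    # initial state is zero: nearest centroid to the origin
    active <- which.min(pre[[1]]$cnorm2)
  }
  u_n <- numeric(pre[[active]]$n)
  w_store <- numeric(grid$N)   # lazily maintained gating values at DEIM nodes

  Nt <- tg$Nt
  coords <- vector("list", Nt)
  cluster_of <- integer(Nt)
  sample_set <- tg$sample_steps
  next_sample <- 1L
  t_cur <- 0

  for (k in seq_len(tg$n_steps)) {
    p <- pre[[active]]
    u_P <- as.numeric(p$PtV %*% u_n)
    w_P <- w_store[p$idx]
    w_P1 <- w_P - dt * gating_rhs(u_P, w_P, ionic)
    w_store[p$idx] <- w_P1
    iapp <- numeric(p$n)
    t_ms <- TIME_SCALE_MS * t_cur
    for (s in p$stim_red)
      if (t_ms >= s$win[1] && t_ms <= s$win[2]) iapp <- iapp + s$r
    rhs <- p$Mr %*% u_n / dt -
      p$E %*% (p$rho_P * ionic_current(u_P, w_P1, ionic)) + iapp
    u_n <- backsolve(p$sys_chol, forwardsolve(t(p$sys_chol), rhs))
    u_n <- as.numeric(u_n)
    if (any(!is.finite(u_n)))
      stop(sprintf("solve_pod_rom: non-finite reduced state at step %d", k))
    t_cur <- t_cur + dt

    if (model$Nc > 1) {
      d2 <- sum(u_n^2) - 2 * as.numeric(p$CtV %*% u_n) + p$cnorm2
      best <- which.min(d2)
      if (best != active) {
        u_n <- as.numeric(cross[[best]][[active]] %*% u_n)
        active <- best
      }
    }
    if (next_sample <= Nt && k == sample_set[next_sample]) {
      coords[[next_sample]] <- u_n
      cluster_of[next_sample] <- active
      next_sample <- next_sample + 1L
    }
  }

  U <- matrix(0, grid$N, Nt)
  for (j in seq_len(Nt))
    U[, j] <- pre[[cluster_of[j]]]$V %*% coords[[j]]
  structure(list(U = U, coords = coords, cluster = cluster_of,
                 times = tg$sample_times, mu = mu),
            class = "rom_trajectory")
}
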