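test_that("energy criterion picks the smallest sufficient dimension", {
  # construct a matrix with singular values {2, 1, 1}
  set.seed(2)
  Qu <- qr.Q(qr(matrix(rnorm(49), 7, 7)))[, 1:3]
  Qv <- qr.Q(qr(matrix(rnorm(36), 6, 6)))[, 1:3]
  S <- Qu %*% diag(c(2, 1, 1)) %*% t(Qv)
  # eps = 0.5: need cumulative energy > 0.75; 4/6 fails, 5/6 passes -> n = 2
  expect_equal(pod_basis(S, eps_pod = 0.5)$n, 2)
  # rank-1 matrix: n = 1 for any eps < 1
  S1 <- outer(rnorm(7), rnorm(6))
  expect_equal(pod_basis(S1, eps_pod = 0.9)$n, 1)
  expect_error(pod_basis(S, eps_pod = 2), "eps_pod")
})

test_that("POD bases are orthonormal with bounded projection residual", {
  set.seed(3)
  S <- matrix(rnorm(50 * 30), 50, 30) %*% diag(exp(-(1:30) / 3))
  for (eps in c(0.3, 0.05, 1e-3)) {
    pb <- pod_basis(S, eps_pod = eps)
    expect_lt(max(abs(crossprod(pb$V) - diag(pb$n))), 1e-10)
    resid <- norm(S - pb$V %*% crossprod(pb$V, S), "F") / norm(S, "F")
    expect_lte(resid, eps + 1e-12)
  }
  # sign convention: first nonzero entry of each mode positive
  pb <- pod_basis(S, eps_pod = 0.05)
  firsts <- apply(pb$V, 2, function(v) v[which(abs(v) > 1e-12)[1]])
  expect_true(all(firsts > 0))
})

test_that("k-means recovers well-separated snapshot groups deterministically", {
  set.seed(4)
  c1 <- rnorm(40); c2 <- c1 + 50
  S <- cbind(replicate(15, c1 + rnorm(40, sd = 0.1)),
             replicate(12, c2 + rnorm(40, sd = 0.1)))
  cl <- cluster_snapshots(S, 2, seed = 11)
  expect_equal(length(unique(cl$labels[1:15])), 1)
  expect_equal(length(unique(cl$labels[16:27])), 1)
  expect_false(cl$labels[1] == cl$labels[16])
  cl2 <- cluster_snapshots(S, 2, seed = 11)
  expect_identical(cl$labels, cl2$labels)
  # Nc = 1 trivially groups everything
  expect_equal(cluster_snapshots(S, 1)$labels, rep(1L, 27))
})

test_that("DEIM is exact on its span and greedy starts at the largest mode entry", {
  set.seed(6)
  F <- matrix(rnorm(40 * 8), 40, 8)
  dm <- deim(F, m = 8)
  expect_equal(length(unique(dm$indices)), 8)
  f <- F %*% rnorm(8)
  expect_lt(max(abs(dm$interpolate(f) - f)), 1e-10)
  # m = 1: the selected index maximizes |Phi_1|
  d1 <- deim(F, m = 1)
  expect_equal(d1$indices, which.max(abs(pod_basis(F, n_fixed = 1)$V)))
  # m = rank: zero interpolation error on every training snapshot
  err <- sapply(seq_len(ncol(F)), function(j)
    max(abs(dm$interpolate(F[, j]) - F[, j])))
  expect_lt(max(err), 1e-10)
})

test_that("local-basis ROM with clusters runs and reconstructs consistently", {
  sc <- tiny_slab_scenario(nx = 12, T_ms = 40, Nt = 40)
  snaps <- snapshot_set(sc, matrix(c(5, 5), 1))
  pod <- build_pod_rom(snaps, eps_pod = 1e-6, Nc = 2, seed = 3)
  expect_equal(pod$Nc, 2)
  expect_true(all(tabulate(pod$labels, 2) > 0))
  rt <- solve_pod_rom(pod, sc, c(5, 5))
  expect_true(all(is.finite(rt$U)))
  expect_equal(dim(rt$U), dim(snaps$S))
  # reconstruction invariant: U column = V_active u_n
  j <- 10
  V <- pod$clusters[[rt$cluster[j]]]$basis$V
  expect_equal(rt$U[, j], as.numeric(V %*% rt$coords[[j]]), tolerance = 1e-12)
  # and the two-cluster ROM tracks the training run
  expect_lt(eps_rel(snaps$S, rt$U), 0.1)
})
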