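make_tiny_fit <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    snaps <- toy_manifold_snapshots(n_side = 8, Nt = 12, mu_values = c(1, 1.5, 2))
    ds <- prepare_dataset(snaps)
    arch <- dlrom_architecture(n = 2, n_mu = 1, image_side = 8,
                               conv_channels = c(4, 8), dfnn_hidden = c(20, 20))
    cfg <- train_config(learning_rate = 1e-3, batch_size = 8, max_epochs = 250,
                        patience = 250, seed = 7)
    cache <<- list(snaps = snaps, ds = ds, arch = arch, cfg = cfg,
                   model = train_dlrom(ds, arch, cfg))
    cache
  }
})

test_that("dataset tensorization pads, masks and round-trips scaling", {
  # N = 10 -> side 4, 6 padded cells
  S <- matrix(runif(10 * 6, -2, 3), 10, 6)
  snaps <- list(S = S, labels = data.frame(t = rep(1:3, 2) / 3,
                                           mu1 = rep(c(0.5, 0.9), each = 3)))
  ds <- prepare_dataset(snaps)
  expect_equal(ds$s, 4L)
  expect_equal(nrow(ds$U), 16)
  expect_equal(ds$mask, c(rep(1, 10), rep(0, 6)))
  expect_true(all(ds$U[11:16, ] == 0))
  expect_true(all(ds$U >= 0 & ds$U <= 1))
  expect_true(all(ds$X >= 0 & ds$X <= 1))
  # unscaling any column is the identity
  back <- ds$U[1:10, ] * (ds$norm$u_max - ds$norm$u_min) + ds$norm$u_min
  expect_equal(back, S, tolerance = 1e-12)
  # perfect-square N needs no padding
  ds2 <- prepare_dataset(list(S = matrix(runif(16 * 4), 16, 4),
                              labels = data.frame(t = c(1:4) / 4,
                                                  mu1 = c(1, 1, 2, 2))))
  expect_equal(ds2$s, 4L)
  expect_equal(sum(ds2$mask), 16)
  expect_error(prepare_dataset(list(S = matrix(1, 4, 3),
                                    labels = data.frame(t = 1:3, mu1 = 1:3))),
               "constant")
})

test_that("loss arithmetic matches the two-term per-example form", {
  u <- matrix(c(2, 0), 2, 1); u_rec <- matrix(c(0, 0), 2, 1)  # ||.||^2 = 4
  ce <- matrix(c(1, 1), 2, 1); cd <- matrix(c(0, 0), 2, 1)    # ||.||^2 = 2
  expect_equal(dlrom_loss(u, u_rec, ce, cd, 0.5), 0.25 * 4 + 0.25 * 2)
  expect_equal(dlrom_loss(u, u_rec, ce, cd, 1), 2)     # pure reconstruction
  expect_equal(dlrom_loss(u, u_rec, ce, cd, 0), 1)     # pure code term
  expect_equal(dlrom_loss(u, u, ce, ce, 0.3), 0)       # perfect match
})

test_that("training is reproducible and checkpoints the best validation loss", {
  fit <- make_tiny_fit()
  m1 <- fit$model
  m2 <- train_dlrom(fit$ds, fit$arch, fit$cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights, m2$weights)
  # training made progress
  expect_lt(min(m1$history$val_loss), m1$history$val_loss[1])
  # best-so-far validation sequence is nonincreasing by construction
  expect_true(all(diff(cummin(m1$history$val_loss)) <= 0))
  expect_equal(m1$best_val_loss, min(m1$history$val_loss), tolerance = 1e-12)
  expect_equal(m1$history$val_loss[m1$best_epoch], m1$best_val_loss)
})

test_that("reported validation loss decomposes into the two loss terms", {
  fit <- make_tiny_fit()
  m <- fit$model; ds <- fit$ds
  idx <- m$val_idx
  # offline recomputation in scaled space through the public evaluation paths
  u_raw <- ds$U[1:ds$N, idx, drop = FALSE] *
    (ds$norm$u_max - ds$norm$u_min) + ds$norm$u_min
  ce <- encode_dlrom(m, u_raw)
  t_raw <- ds$labels$t[idx]
  mu_raw <- matrix(ds$labels$mu1[idx], ncol = 1)
  cd <- latent_coordinates(m, t_raw, mu_raw)
  pred <- predict_dlrom(m, t_raw, mu_raw)
  pred_sc <- (pred - ds$norm$u_min) / (ds$norm$u_max - ds$norm$u_min)
  pred_sc <- rbind(pred_sc, matrix(0, ds$s^2 - ds$N, length(idx)))
  offline <- dlrom_loss(ds$U[, idx], pred_sc, ce, cd, fit$cfg$omega_h)
  expect_equal(offline, m$best_val_loss, tolerance = 1e-6)
})

test_that("prediction is stateless, encoder-free and shape-correct", {
  fit <- make_tiny_fit()
  m <- fit$model
  p <- predict_dlrom(m, c(0.2, 0.8), c(1.5))
  expect_equal(dim(p), c(m$N, 2L))
  expect_true(all(is.finite(p)))
  # out-of-order queries give identical values (no hidden time stepping)
  q <- predict_dlrom(m, c(0.8, 0.2), c(1.5))
  expect_identical(p, q[, 2:1])
  expect_warning(predict_dlrom(m, 5, c(1.5)), "training range")
  # codes: dfnn output length n; encoder agrees on training samples
  expect_equal(nrow(latent_coordinates(m, 0.5, c(1.2))), 2L)
  expect_equal(nrow(encode_dlrom(m, fit$snaps$S[, 1])), 2L)
})

test_that("autoencoder consistency holds after training on the tiny manifold", {
  fit <- make_tiny_fit()
  m <- fit$model; snaps <- fit$snaps
  # decoder(dfnn) reconstructs training snapshots to modest relative error
  pred <- predict_trajectory(m, snaps$labels$t[1:12], 1)
  rel <- norm(snaps$S[, 1:12] - pred, "F") / norm(snaps$S[, 1:12], "F")
  expect_lt(rel, 0.5)
  # code mismatch between encoder and dfnn is small relative to code norm
  ce <- encode_dlrom(m, snaps$S[, 1:12])
  cd <- latent_coordinates(m, snaps$labels$t[1:12],
                           matrix(snaps$labels$mu1[1:12], ncol = 1))
  expect_lt(stats::median(sqrt(colSums((ce - cd)^2))) /
              stats::median(sqrt(colSums(cd^2)) + 1e-12), 1)
})

test_that("models save to and load from a directory archive", {
  fit <- make_tiny_fit()
  dir <- tempfile()
  save_dlrom(fit$model, dir)
  expect_true(all(file.exists(file.path(dir, c("weights.rds", "model.json",
                                               "history.csv")))))
  m2 <- load_dlrom(dir)
  expect_equal(predict_dlrom(m2, c(0.3), c(1.5)),
               predict_dlrom(fit$model, c(0.3), c(1.5)))
})
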