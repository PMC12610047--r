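test_that("the sparse MSE loss vanishes iff all three terms vanish", {
  cfg <- spdae_config(hidden_units = 3)
  withr::with_seed(1, x <- matrix(rnorm(20), 5))
  rho <- cfg$sparsity_proportion
  expect_equal(sparse_mse_loss(x, x, list(), rep(rho, 3), cfg), 0)
  # KL(0.05 || 0.05) = 0; KL(0.05 || 0.10) by direct closed-form evaluation
  expect_equal(sparse_mse_loss(x, x, list(), c(rho, 0.10, rho), cfg),
               0.05 * log(0.5) + 0.95 * log(0.95 / 0.90), tolerance = 1e-10)
  expect_equal(0.05 * log(0.5) + 0.95 * log(0.95 / 0.90), 0.0167,
               tolerance = 1e-2)
  # weight decay term
  w <- matrix(2, 2, 2)
  expect_equal(sparse_mse_loss(x, x, list(w), rep(rho, 3), cfg),
               cfg$l2 * 16)
  # saturated activations are clamped with a warning
  expect_warning(v <- sparse_mse_loss(x, x, list(), c(rho, 1, rho), cfg),
                 "clamped")
  expect_true(is.finite(v))
})

test_that("conjugate-gradient pretraining reduces the autoencoder loss", {
  ss <- subset_segments(tiny_segments(), 1:30)
  x <- flatten_segments(ss)
  cfg <- spdae_config(hidden_units = 8, max_epochs = 25, seed = 4)
  pre <- pretrain_encoder(x, cfg, optimizer = "cg")
  expect_lt(pre$history[length(pre$history)], pre$history[1])
  expect_equal(dim(pre$We), c(ncol(x), 8L))
  # pretraining gradient matches finite differences at a random point
  obj <- spdae_objective(x, x, ncol(x), 4L, spdae_config(hidden_units = 4))
  withr::with_seed(2, theta <- rnorm(ncol(x) * 4 + 4 + 4 * ncol(x) + ncol(x),
                                     sd = 0.05))
  g <- obj$gr(theta)
  withr::with_seed(3, pick <- sample(length(theta), 12))
  for (k in pick) {
    tp <- theta; tp[k] <- tp[k] + 1e-6
    tm <- theta; tm[k] <- tm[k] - 1e-6
    num <- (obj$fn(tp) - obj$fn(tm)) / 2e-6
    expect_lt(abs(num - g[k]) / max(1e-6, abs(num) + abs(g[k])), 1e-4)
  }
})

test_that("the two-phase Sp-DAE trainer yields a working classifier", {
  ss <- balance_dataset(tiny_segments(), balance_config(seed = 3))
  arch <- build_spdae(spdae_config(hidden_units = 16, max_epochs = 30,
                                   seed = 6))
  m <- train_spdae(ss, arch, head_config = train_config(max_epochs = 6L,
                                                        seed = 6))
  expect_s3_class(m, "har_model")
  expect_length(m$pretrain_history, 2L)  # cg start/end loss
  expect_lt(m$history$loss[6], m$history$loss[1])
  pred <- predict(m, subset_segments(ss, 1:5))
  expect_equal(rowSums(as.matrix(pred[, -1])), rep(1, 5), tolerance = 1e-6)
  # decoder retained for inspection but absent from the classifier spec
  expect_equal(dim(m$decoder$W), c(16L, 2400L))
})

test_that("the recurrent Sp-DAE trains in both feature wirings", {
  ss <- subset_segments(tiny_segments(), 1:40)
  for (feat in c("window", "timestep")) {
    enc_h <- 8L
    spec <- build_recurrent_spdae(enc_h, 4L, features = feat)
    m <- train_recurrent_spdae(
      ss, spec,
      spdae_cfg = spdae_config(hidden_units = enc_h, max_epochs = 10,
                               seed = 2),
      head_config = train_config(max_epochs = 3L, seed = 2),
      max_pretrain_rows = 500L)
    expect_s3_class(m, "har_model")
    expect_true(all(is.finite(m$history$loss)))
  }
  expect_error(train_recurrent_spdae(
    ss, build_recurrent_spdae(8, 4),
    spdae_cfg = spdae_config(hidden_units = 9)), "disagree")
})
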