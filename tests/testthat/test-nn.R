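test_that("analytic gradients match central finite differences", {
  loss_of <- function(spec, params, x, y_idx) {
    fw <- forward_pass(spec, params, x)
    -mean(log(fw$probs[cbind(seq_len(dim(x)[1]), y_idx)]))
  }
  for (spec in list(build_bilstm(3, n_in = 3, win = 6),
                    build_rcnn(4, input_shape = c(8L, 20L)),
                    build_deepconvlstm(3, n_in = 4, win = 24))) {
    withr::with_seed(42, {
      n <- 2L
      x <- array(rnorm(n * prod(spec$input_shape)),
                 dim = c(n, spec$input_shape))
      y_idx <- sample(spec$n_classes, n, replace = TRUE)
    })
    params <- init_params(spec, seed = 9)
    fw <- forward_pass(spec, params, x)
    y1 <- matrix(0, 2L, spec$n_classes)
    y1[cbind(1:2, y_idx)] <- 1
    sm <- which(vapply(spec$layers, `[[`, "", "kind") == "softmax")
    ga <- backward_pass(spec, params, fw,
                        array((fw$probs - y1) / 2, dim = c(2L, 7L, 1L)),
                        from = sm - 1L)$grads
    theta <- unlist(params, use.names = FALSE)
    gvec <- unlist(ga, use.names = FALSE)
    withr::with_seed(1, pick <- sample(length(theta), 25))
    eps <- 1e-6
    rel_err <- vapply(pick, function(k) {
      tp <- theta; tp[k] <- tp[k] + eps
      tm <- theta; tm[k] <- tm[k] - eps
      num <- (loss_of(spec, utils::relist(tp, params), x, y_idx) -
                loss_of(spec, utils::relist(tm, params), x, y_idx)) / (2 * eps)
      abs(num - gvec[k]) / max(1e-4, abs(num) + abs(gvec[k]))
    }, 0)
    expect_lt(max(rel_err), 1e-3, label = paste(spec$name, "gradient error"))
  }
})

test_that("softmax rows are probability distributions for any model", {
  ss <- subset_segments(tiny_segments(), 1:8)
  for (spec in list(build_bilstm(4), build_rcnn(4))) {
    model <- structure(list(spec = spec, params = init_params(spec, 3),
                            classes = activity_classes()),
                       class = "har_model")
    pred <- predict(model, ss)
    probs <- as.matrix(pred[, -1])
    expect_true(all(probs >= 0))
    expect_equal(rowSums(probs), rep(1, 8), tolerance = 1e-6)
    expect_length(pred$.pred, 8L)
  }
})

test_that("prediction rejects mismatched window shapes", {
  model <- make_fixtures(seed = 2, n_subjects = 1, epochs = 1)$model
  expect_error(predict(model, array(0, c(2, 5, 240))), "shape mismatch")
})

test_that("training is deterministic, decreases the loss, and records history", {
  ss <- tiny_segments()
  cfg <- train_config(max_epochs = 4L, seed = 77)
  m1 <- train_network(ss, build_bilstm(6), cfg)
  m2 <- train_network(ss, build_bilstm(6), cfg)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(m1$params, m2$params)
  expect_equal(nrow(m1$history), 4L)
  expect_true(all(is.finite(m1$history$loss)))
  expect_lt(m1$history$loss[4], m1$history$loss[1])
  # the printed schedule: lr drops by 0.1 every lr_drop_period epochs
  m3 <- train_network(ss, build_bilstm(4),
                      train_config(max_epochs = 12L, lr_drop_period = 5L,
                                   seed = 1))
  expect_equal(unique(m3$history$lr), c(1e-3, 1e-4, 1e-5))
})

test_that("degenerate training sets are rejected", {
  ss <- tiny_segments()
  only_n <- subset_segments(ss, ss$y == "N")
  expect_error(train_network(only_n, build_bilstm(4)), "degenerate")
  expect_error(train_config(max_epochs = 0), "max_epochs")
})

test_that("frozen layers keep their pretrained weights", {
  ss <- subset_segments(tiny_segments(), 1:20)
  spec <- build_recurrent_spdae(6, 4)
  params <- init_params(spec, seed = 5)
  enc_at <- which(vapply(spec$layers, `[[`, "", "kind") == "encoder_dense")
  m <- train_network(ss, spec, train_config(max_epochs = 2L, seed = 5),
                     init = params, frozen_layers = enc_at)
  expect_identical(m$params[[enc_at]], params[[enc_at]])
  # and unfrozen layers moved
  dense_at <- which(vapply(spec$layers, `[[`, "", "kind") == "dense")
  expect_false(identical(m$params[[dense_at]], params[[dense_at]]))
})

test_that("every builder's runtime shapes agree with the analytic profiler", {
  ss <- subset_segments(tiny_segments(), 1:3)
  specs <- list(build_bilstm(5), build_rcnn(4), build_deepconvlstm(4),
                build_recurrent_spdae(6, 3),
                build_spdae(spdae_config(hidden_units = 6))$classifier)
  for (spec in specs) {
    params <- init_params(spec, seed = 2)
    expect_equal(n_params(params), count_learnables(spec),
                 info = spec$name)
    fw <- forward_pass(spec, params, ss$x)
    expect_equal(dim(fw$probs), c(3L, 7L), info = spec$name)
  }
})

test_that("the reversed input drives the backward direction of the BiLSTM", {
  withr::with_seed(6, {
    d <- 3L; h <- 4L; tl <- 5L
    p <- list(fwd = init_rnn_dir(d, h, 4L, TRUE),
              bwd = init_rnn_dir(d, h, 4L, TRUE))
    x <- matrix(rnorm(d * tl), d, tl)
  })
  out <- rnn_forward_oracle("bilstm", p, x)
  # backward rows on x equal forward-direction states on reversed x, re-reversed
  fwd_on_rev <- rnn_forward_oracle("lstm", p$bwd, x[, tl:1])
  expect_equal(out[h + 1:h, ], fwd_on_rev[, tl:1], tolerance = 1e-12)
})
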