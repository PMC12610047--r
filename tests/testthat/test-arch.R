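test_that("the BiLSTM classifier has the canonical five-layer stack", {
  spec <- build_bilstm(300)
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  expect_identical(kinds, c("sequence_input", "bilstm", "dense", "softmax",
                            "classification_output"))
  sh <- infer_shapes(spec)
  expect_identical(sh$output[2], "600 x 1 (seq)")   # 2h, last state
  expect_identical(sh$output[3], "7 x 1 (seq)")
  expect_equal(spec$n_classes, 7L)
  expect_error(build_bilstm(0), "hidden_units")
})

test_that("the RCNN stacks 14 layers with the stated conv geometry", {
  spec <- build_rcnn(100)
  expect_length(spec$layers, 14L)
  sh <- infer_shapes(spec)
  expect_identical(sh$output[3], "8 x 238 x 32 (img)")
  expect_identical(sh$output[6], "4 x 59 x 32 (img)")
  expect_identical(sh$output[10], "7552 x 1 (seq)")
  # an input too small for the dilated second conv errors, naming the layer
  expect_error(build_rcnn(10, input_shape = c(6L, 8L)), "conv2d")
})

test_that("DeepConvLSTM shrinks the time axis 240 -> 224 into 640-wide features", {
  spec <- build_deepconvlstm(128)
  sh <- infer_shapes(spec)
  expect_identical(sh$output[6], "10 x 224 x 64 (img)")
  expect_identical(sh$output[8], "640 x 224 (seq)")
  expect_identical(sh$output[9], "128 x 224 (seq)")  # first LSTM keeps time
  expect_identical(sh$output[10], "128 x 1 (seq)")
})

test_that("the Sp-DAE pair shares the encoder and discards the decoder", {
  arch <- build_spdae(spdae_config(hidden_units = 2000))
  p <- init_params(arch$autoencoder, seed = 1)
  enc <- which(vapply(arch$autoencoder$layers, `[[`, "", "kind") ==
                 "encoder_dense")
  expect_equal(dim(p[[enc]]$W), c(2400L, 2000L))
  # classifier: no layer maps back to the 2400-dim input
  clf_outs <- vapply(arch$classifier$layers, function(l) {
    if (!is.null(l$params$out)) l$params$out else NA_integer_
  }, 1L)
  expect_false(any(clf_outs == 2400L, na.rm = TRUE))
  expect_identical(infer_shapes(arch$classifier)$output[4], "7 x 1 (seq)")
})

test_that("recurrent Sp-DAE wires the encoder into the BiLSTM in both modes", {
  win <- build_recurrent_spdae(1300, 300)
  sh <- infer_shapes(win)
  expect_identical(sh$output[3], "1300 x 1 (seq)")   # one feature vector
  expect_identical(sh$output[4], "600 x 1 (seq)")
  ts <- build_recurrent_spdae(16, 8, features = "timestep")
  sh2 <- infer_shapes(ts)
  expect_identical(sh2$output[2], "16 x 240 (seq)")  # encoded sequence
  expect_identical(sh2$output[3], "16 x 1 (seq)")
})

test_that("specs survive serialization with all hyperparameters intact", {
  for (spec in list(build_bilstm(3), build_rcnn(4),
                    build_recurrent_spdae(6, 3))) {
    rt <- unserialize(serialize(spec, NULL))
    expect_identical(rt, spec)
    expect_identical(infer_shapes(rt), infer_shapes(spec))
  }
})

test_that("unknown layer kinds are rejected", {
  expect_error(layer("pooling"), "unsupported layer kind")
})
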