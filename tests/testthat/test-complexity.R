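test_that("learnable-parameter closed forms follow the layer formulas", {
  # bidirectional LSTM: 8h(d + h + 1) plus the dense head (2h + 1) * 7
  expect_identical(count_learnables(build_bilstm(1)),
                   8L * (10L + 1L + 1L) + 3L * 7L)
  # dense 600 -> 7 alone
  spec <- new_arch_spec("d600", list(layer("sequence_input"),
                                     layer("flatten", keep_time = FALSE),
                                     layer("dense", out = 7L)),
                        c(600L, 1L), 7L)
  expect_identical(count_learnables(spec), 4207L)
  # conv2d 3x3, 32 filters on one channel
  conv <- new_arch_spec("c", list(layer("sequence_input"), layer("seq_fold"),
                                  layer("conv2d", filters = 32L,
                                        kernel = c(3L, 3L),
                                        stride = c(1L, 1L),
                                        dilation = c(1L, 1L))),
                        c(10L, 240L), 7L)
  expect_identical(count_learnables(conv), 320L)
})

test_that("memory footprint uses the 4-byte MiB convention", {
  expect_identical(memory_mb(0), 0)
  expect_identical(memory_mb(1048576 / 4), 1)
  expect_error(memory_mb(-1), ">= 0")
})

test_that("latency is operations over derated attainable throughput", {
  expect_equal(latency_estimate(1e9, 1e9, efficiency = 1), 1)
  expect_equal(latency_estimate(1e9, 1e9), 1 / 0.7, tolerance = 1e-12)
  expect_equal(latency_estimate(0, 5e9), 0)
  expect_error(latency_estimate(10, 0), "attainable")
  expect_error(latency_estimate(10, 1e9, efficiency = 1.2), "efficiency")
})

test_that("MAC and MA follow the documented convention on hand-counted layers", {
  d600 <- new_arch_spec("d", list(layer("sequence_input"),
                                  layer("flatten", keep_time = FALSE),
                                  layer("dense", out = 7L)), c(600L, 1L), 7L)
  expect_equal(count_mac(d600), 4200)
  # dense 3 -> 2: 6 multiplications + 4 accumulation adds + 2 bias adds
  d32 <- new_arch_spec("d2", list(layer("sequence_input"),
                                  layer("flatten", keep_time = FALSE),
                                  layer("dense", out = 2L)), c(3L, 1L), 7L)
  expect_equal(count_ma(d32), 12)
  # 2x2 single-filter conv on 3x3 input: 2x2 output x 4 products
  conv <- new_arch_spec("c", list(layer("sequence_input"), layer("seq_fold"),
                                  layer("conv2d", filters = 1L,
                                        kernel = c(2L, 2L),
                                        stride = c(1L, 1L),
                                        dilation = c(1L, 1L))),
                        c(3L, 3L), 7L)
  expect_equal(count_mac(conv), 16)
  oc <- ops_oracle(conv)
  expect_equal(oc$mac, 16)
})

test_that("the report aggregates per-layer rows consistently", {
  rep_ <- complexity_report(build_bilstm(300))
  expect_equal(rep_$lp, sum(tidy(rep_)$lp))
  expect_equal(rep_$ma, sum(tidy(rep_)$ma))
  expect_equal(rep_$memory_mb, memory_mb(rep_$lp))
  expect_equal(glance(rep_)$lp, 750607)
  expect_error(count_learnables(structure(list(
    name = "bad", layers = list(layer("sequence_input")),
    input_shape = c(10L, 240L), n_classes = 7L), class = "arch_spec")),
    NA)
})

test_that("adding a layer never decreases LP, MAC, or MA", {
  base_layers <- list(layer("sequence_input"),
                      layer("bilstm", h = 5L, return_sequence = TRUE))
  grown <- list(
    c(base_layers, list(layer("dense", out = 7L))),
    c(base_layers, list(layer("gru", h = 4L, return_sequence = FALSE),
                        layer("dense", out = 7L))),
    c(base_layers, list(layer("gru", h = 4L, return_sequence = FALSE),
                        layer("dense", out = 7L), layer("softmax"))))
  stats_of <- function(ly) {
    sp <- new_arch_spec("g", ly, c(6L, 12L), 7L)
    c(count_learnables(sp), count_mac(sp), count_ma(sp))
  }
  prev <- c(0, 0, 0)
  for (ly in grown) {
    cur <- stats_of(ly)
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("LP equals the runtime parameter store for every builder", {
  specs <- list(build_bilstm(7), build_rcnn(5), build_deepconvlstm(6),
                build_recurrent_spdae(9, 4),
                build_spdae(spdae_config(hidden_units = 5))$classifier,
                build_spdae(spdae_config(hidden_units = 5))$autoencoder)
  for (spec in specs) {
    expect_identical(n_params(init_params(spec, 1)),
                     as.integer(count_learnables(spec)), )
  }
})
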