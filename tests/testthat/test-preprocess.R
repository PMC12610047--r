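probe <- function(freq, fs, dur = 2) {
  sin(2 * pi * freq * seq(0, dur, by = 1 / fs))
}
rms <- function(x) sqrt(mean(x^2))

test_that("the notch filter suppresses 50 Hz and passes the band", {
  fs <- 2000
  tone50 <- probe(50, fs)
  expect_lte(rms(notch_filter(tone50, fs)), 0.1 * rms(tone50))
  tone5 <- probe(5, fs)
  expect_equal(rms(notch_filter(tone5, fs)) / rms(tone5), 1, tolerance = 0.05)
  expect_identical(notch_filter(rep(0, 100), fs), rep(0, 100))
  expect_error(notch_filter(tone5, fs = 80, f0 = 50), "Nyquist")
})

test_that("the Butterworth band-pass passes 100 Hz and rejects out-of-band probes", {
  fs <- 2000
  r100 <- rms(bandpass_butterworth(probe(100, fs), fs)) / rms(probe(100, fs))
  expect_true(r100 >= 0.95 && r100 <= 1.05)
  expect_lte(rms(bandpass_butterworth(probe(5, fs), fs)) / rms(probe(5, fs)),
             0.1)
  expect_lte(rms(bandpass_butterworth(probe(900, fs), fs)) /
               rms(probe(900, fs)), 0.1)
  expect_identical(bandpass_butterworth(rep(0, 64), fs), rep(0, 64))
  expect_error(bandpass_butterworth(probe(5, fs), fs, hi = 1000), "Nyquist")
})

test_that("filters are linear and phase-free in length", {
  fs <- 2000
  withr::with_seed(8, x <- rnorm(500))
  for (f in list(function(v) notch_filter(v, fs),
                 function(v) bandpass_butterworth(v, fs))) {
    expect_length(f(x), length(x))
    expect_equal(f(3.7 * x), 3.7 * f(x), tolerance = 1e-9)
  }
})

test_that("rectification is the idempotent absolute value", {
  expect_identical(rectify(c(-1, 2, -3)), c(1, 2, 3))
  expect_identical(rectify(rep(0, 5)), rep(0, 5))
  withr::with_seed(2, x <- rnorm(100))
  expect_identical(rectify(rectify(x)), rectify(x))
})

test_that("MVC normalization divides by the contraction reference", {
  expect_equal(mvc_normalize(0.5, 0.5), 1)
  x <- c(0.1, 0.4, 0.9)
  expect_identical(mvc_normalize(x, 1), x)
  expect_equal(mvc_normalize(x, 2), x / 2)
  expect_error(mvc_normalize(x, 0), "mvc")
})

test_that("the RMS envelope matches its definition", {
  expect_equal(rms_envelope(rep(-3, 100), fs = 1000), rep(3, 100))
  # unit sinusoid, window >> period: interior ~ 1/sqrt(2)
  fs <- 2000
  x <- probe(100, fs)
  env <- rms_envelope(x, fs, window_ms = 250)
  interior <- env[500:(length(env) - 500)]
  expect_equal(mean(interior), 1 / sqrt(2), tolerance = 1e-3)
  expect_error(rms_envelope(numeric(0), 1000), "empty")
})

test_that("the RMS envelope equals the brute-force sliding-window oracle", {
  rms_oracle <- function(x, w) {
    n <- length(x)
    half_lo <- (w - 1L) %/% 2L; half_hi <- w - 1L - half_lo
    vapply(seq_len(n), function(i) {
      win <- x[max(1L, i - half_lo):min(n, i + half_hi)]
      sqrt(mean(win^2))
    }, 0)
  }
  withr::with_seed(31, {
    for (k in 1:100) {
      n <- sample(20:200, 1)
      w_ms <- sample(5:80, 1)
      fs <- 1000
      x <- rnorm(n) * runif(1, 0.1, 10)
      w <- as.integer(round(w_ms * fs / 1000))
      expect_lt(max(abs(rms_envelope(x, fs, w_ms) - rms_oracle(x, w))),
                1e-9)
    }
  })
})

test_that("resampling to the kinematic clock preserves duration and values", {
  expect_equal(resample_to_240(rep(1, 2000), 2000), rep(1, 240),
               tolerance = 1e-6)
  x <- rnorm(240)
  expect_identical(resample_to_240(x, 240), x)
  ramp <- seq(0, 1, length.out = 2000)
  out <- resample_to_240(ramp, 2000)
  expect_length(out, 240)
  expect_equal(out[1], 0, tolerance = 0.01)
  expect_equal(out[length(out)], 1, tolerance = 0.01)
  expect_error(resample_to_240(x, 100), "upsampling")
})

test_that("early fusion stacks 10 canonical channels over aligned labels", {
  s <- tiny_cohort()[[1]]
  fused <- fuse_channels(s)
  expect_equal(nrow(fused$data), 10L)
  expect_equal(ncol(fused$data), length(fused$labels))
  expect_identical(rownames(fused$data), channel_names())
  # sEMG rows are envelopes: non-negative
  expect_true(all(fused$data[9:10, ] >= 0))
  expect_error(fuse_channels(s, matrix(0, 2, 10)), "alignment")
})

test_that("windowing yields floor((T - win)/stride) + 1 majority-labeled segments", {
  s <- generate_session(mmh_protocol("N", 5), subject_params(seed = 3))
  fused <- fuse_channels(s)
  ss <- segment_windows(fused)
  expect_equal(n_segments(ss), 5L)                   # 1200 / 240

  fused2 <- fused
  fused2$data <- fused$data[, 1:1000]
  fused2$labels <- fused$labels[1:1000]
  expect_equal(n_segments(segment_windows(fused2)), 4L)  # remainder dropped

  # majority label with 130 LF vs 110 N samples
  fused3 <- fused2
  fused3$labels <- activity_factor(rep(c("N", "LF"), c(110, 890)))
  expect_equal(as.character(segment_windows(fused3)$y[1]), "LF")

  # exact 120/120 tie broken toward the window's centre sample (an N here)
  fused4 <- fused2
  fused4$labels <- activity_factor(rep(c("N", "LF"), c(120, 880)))
  expect_equal(as.character(segment_windows(fused4)$y[1]), "N")

  expect_warning(out <- segment_windows(list(data = fused$data[, 1:100],
                                             labels = fused$labels[1:100],
                                             subject_id = "S")),
                 "shorter")
  expect_equal(n_segments(out), 0L)
})

test_that("windows tile a prefix of the series without overlap", {
  ss <- tiny_segments()
  s <- tiny_cohort()[[1]]
  fused <- fuse_channels(s)
  seg <- segment_windows(fused)
  n <- n_segments(seg)
  for (k in c(1L, n %/% 2L, n)) {
    expect_equal(seg$x[k, , ], fused$data[, (k - 1) * 240 + 1:240],
                 ignore_attr = TRUE)
  }
})

test_that("segment sets round-trip through the CSV layout", {
  ss <- subset_segments(tiny_segments(), 1:5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_segments(ss, path)
  r <- read_segments(path)
  expect_equal(r$x, ss$x, tolerance = 1e-15)
  expect_identical(as.character(r$y), as.character(ss$y))
  expect_identical(r$subject_id, ss$subject_id)
})
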