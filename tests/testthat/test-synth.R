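test_that("a session follows its protocol at the 240 Hz label clock", {
  s <- generate_session(mmh_protocol("N", 5), subject_params(seed = 7))
  expect_length(s$labels, 1200)                       # 5 s x 240 Hz
  expect_true(all(s$labels == "N"))
  expect_equal(dim(s$kin), c(8L, 1200L))
  expect_equal(ncol(s$semg) / s$semg_rate_hz, 1200 / 240, tolerance = 1e-9)
  expect_identical(s$channel_names, channel_names())

  proto <- mmh_protocol(c("N", "LF", "K"), c(1, 2, 1.5), c(0, 10, 10))
  s2 <- generate_session(proto, subject_params(seed = 1))
  expect_equal(as.character(unique(s2$labels)), c("N", "LF", "K"))
  expect_equal(sum(s2$labels == "LF"), 480)
})

test_that("identical protocol, params and seed reproduce a session bit-for-bit", {
  proto <- default_protocol(cycles = 1)
  p <- subject_params(seed = 99)
  a <- generate_session(proto, p)
  b <- generate_session(proto, p)
  expect_identical(a$kin, b$kin)
  expect_identical(a$semg, b$semg)
  expect_identical(a$labels, b$labels)
})

test_that("mean rectified sEMG amplitude grows with the handled load", {
  p <- subject_params(seed = 5)
  heavy <- generate_session(mmh_protocol("K", 2, 10), p)
  light <- generate_session(mmh_protocol("K", 2, 1), p)
  expect_gt(mean(abs(heavy$semg)), mean(abs(light$semg)))
})

test_that("invalid protocols and parameters are rejected", {
  expect_error(mmh_protocol("N", -1), "duration")
  expect_error(mmh_protocol("XX", 1), "unknown activity class")
  expect_error(subject_params(mvc = 0), "mvc")
  expect_error(generate_cohort(0), "n_subjects")
})

test_that("a cohort has distinct subjects and the configured N-pose dominance", {
  co <- generate_cohort(14, default_protocol(cycles = 1), master_seed = 3,
                        imbalance_n_fraction = 0.4)
  expect_length(co, 14)
  ids <- vapply(co, `[[`, "", "subject_id")
  expect_length(unique(ids), 14)
  census <- cohort_label_census(co)
  expect_gte(census$fraction[census$activity == "N"], 0.4)
  # single-subject cohort degenerates cleanly
  expect_length(generate_cohort(1, default_protocol(cycles = 1),
                                master_seed = 3), 1)
})

test_that("cohorts are a pure function of their seeds", {
  a <- generate_cohort(2, default_protocol(cycles = 1), master_seed = 11)
  b <- generate_cohort(2, default_protocol(cycles = 1), master_seed = 11)
  expect_identical(a[[1]]$kin, b[[1]]$kin)
  expect_identical(a[[2]]$semg, b[[2]]$semg)
  c2 <- generate_cohort(2, default_protocol(cycles = 1), master_seed = 12)
  expect_false(identical(a[[1]]$kin, c2[[1]]$kin))
})

test_that("with low noise the classes are separable by a nearest-centroid rule", {
  co <- generate_cohort(2, default_protocol(cycles = 2), master_seed = 21,
                        noise_sd = 0.001)
  ss <- preprocess_cohort(co)
  sp <- split_70_30(ss, seed = 4)
  expect_gte(nearest_centroid_f1(sp$train, sp$test), 0.97)
})

test_that("sessions round-trip through the CSV layout", {
  s <- generate_session(mmh_protocol(c("N", "W"), c(1, 1), c(0, 5)),
                        subject_params(subject_id = "S42", seed = 13))
  dir <- withr::local_tempdir()
  write_session(s, dir)
  r <- read_session(dir)
  expect_identical(r$subject_id, "S42")
  expect_equal(r$kin, s$kin, ignore_attr = TRUE)
  expect_equal(r$semg, s$semg, ignore_attr = TRUE)
  expect_identical(as.character(r$labels), as.character(s$labels))
  expect_identical(r$semg_rate_hz, s$semg_rate_hz)
})
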