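test_that("down-sampling reduces one class to the target and nothing else", {
  ss <- tiny_segments()
  n_n <- sum(ss$y == "N")
  out <- downsample_class(ss, "N", 5L, seed = 3)
  cc <- class_counts(out)
  expect_equal(cc$n[cc$activity == "N"], 5L)
  for (cls in setdiff(activity_classes(), "N")) {
    expect_equal(sum(out$y == cls), sum(ss$y == cls))
  }
  # target == current is the identity
  same <- downsample_class(ss, "N", n_n, seed = 3)
  expect_equal(n_segments(same), n_segments(ss))
  # deterministic per seed
  expect_identical(downsample_class(ss, "N", 5L, seed = 3)$x, out$x)
  expect_error(downsample_class(ss, "N", n_n + 1L, seed = 3), "exceeds")
})

test_that("augmentation cycles sources, preserves originals, and scales noise", {
  ss <- tiny_segments()
  cfg <- balance_config(noise_sd_fraction = 0.05, seed = 5)
  n_lf <- sum(ss$y == "LF")
  out <- augment_class(ss, "LF", n_lf + 4L, cfg)
  expect_equal(sum(out$y == "LF"), n_lf + 4L)
  # originals are bit-identical, synthetic copies appended at the end
  expect_identical(out$x[seq_len(n_segments(ss)), , ], ss$x)
  expect_identical(augment_class(ss, "LF", n_lf, cfg)$x, ss$x)
  expect_error(augment_class(subset_segments(ss, ss$y == "N"), "LF", 3, cfg),
               "cannot augment")

  # noise scale: sd of (copy - source) ~ noise_sd_fraction x channel sd
  src_idx <- which(ss$y == "LF")
  big <- augment_class(ss, "LF", n_lf + 100L, cfg)
  new_idx <- (n_segments(ss) + 1L):n_segments(big)
  ratios <- vapply(seq_along(new_idx), function(j) {
    src <- ss$x[src_idx[((j - 1L) %% n_lf) + 1L], , ]
    diff <- big$x[new_idx[j], , ] - src
    mean(apply(diff, 1L, stats::sd) / (0.05 * apply(src, 1L, stats::sd)))
  }, 0)
  expect_lt(abs(mean(ratios) - 1), 0.2)
})

test_that("balancing equalizes all seven classes and never edits survivors", {
  ss <- study_segments()
  cfg <- balance_config(seed = 9)
  out <- balance_dataset(ss, cfg)
  cc <- class_counts(out)
  expect_lte(max(cc$n) / min(cc$n), cfg$max_ratio)
  expect_equal(length(unique(cc$n)), 1L)  # median rule gives exact equality

  # every surviving original equals its source bit-for-bit: match by
  # fingerprint of the first channel
  key <- function(x) apply(x, 1L, function(w) paste0(signif(w[1, 1:4], 15),
                                                     collapse = "|"))
  src_keys <- key(ss$x)
  out_keys <- key(out$x)
  surv <- out_keys %in% src_keys
  expect_gt(sum(surv), 0)
  m <- match(out_keys[surv], src_keys)
  expect_identical(out$x[which(surv), , ], ss$x[m, , ])

  # deterministic given the seed
  out2 <- balance_dataset(ss, balance_config(seed = 9))
  expect_identical(out$x, out2$x)

  # missing class errors by name
  no_k <- subset_segments(ss, ss$y != "K")
  expect_error(balance_dataset(no_k, cfg), "missing class.*K")
})

test_that("after balancing, micro and macro F1 of random guessing coincide", {
  ss <- balance_dataset(tiny_segments(), balance_config(seed = 2))
  withr::with_seed(14, {
    reps <- replicate(200, {
      pred <- sample(activity_classes(), n_segments(ss), replace = TRUE)
      cm <- confusion(ss$y, pred)
      c(macro = macro_f1(cm), micro = accuracy(cm))
    })
  })
  # on balanced classes both concentrate near 1/7
  expect_lt(abs(mean(reps["macro", ]) - mean(reps["micro", ])), 0.02)
})
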