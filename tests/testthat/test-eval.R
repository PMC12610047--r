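test_that("confusion matrices count true/predicted pairs", {
  y <- rep(activity_classes(), each = 3)
  cm <- confusion(y, y)
  expect_equal(sum(diag(cm)), 21)
  expect_equal(sum(cm), 21)
  # absent class has a zero row; order of items is irrelevant
  cm2 <- confusion(c("N", "LF"), c("N", "N"))
  expect_equal(sum(cm2["K", ]), 0)
  perm <- c(2, 1)
  expect_identical(confusion(c("N", "LF")[perm], c("N", "N")[perm]), cm2)
  expect_error(confusion("N", c("N", "LF")), "length mismatch")
})

test_that("macro F1 matches hand-computed values", {
  # perfect diagonal
  expect_equal(macro_f1(diag(c(3, 5, 2, 1, 4, 2, 6))), 1)
  # hand-worked two-class case: P = (1, 2/3), R = (1/2, 1)
  cm <- matrix(c(1, 0, 1, 2), 2, 2,
               dimnames = list(true = c("a", "b"), pred = c("a", "b")))
  expect_equal(macro_f1(cm), (2 / 3 + 4 / 5) / 2, tolerance = 1e-12)
  expect_equal(macro_f1(cm), 0.7333, tolerance = 1e-4)
  expect_equal(accuracy(cm), 3 / 4)
  expect_equal(macro_precision(cm), (1 + 2 / 3) / 2)
  expect_error(macro_f1(matrix(0, 2, 2)), "all-zero")
  # a class absent from truth and prediction scores 0 with a warning
  cm3 <- confusion(c("N", "LF"), c("N", "LF"))
  expect_warning(v <- macro_f1(cm3), "F1 = 0")
  expect_equal(v, 2 / 7)
})

test_that("uniform random predictions on balanced classes give macro F1 near 1/7", {
  withr::with_seed(99, {
    n <- 1e5
    y <- sample(activity_classes(), n, replace = TRUE)
    p <- sample(activity_classes(), n, replace = TRUE)
  })
  expect_equal(macro_f1(confusion(y, p)), 1 / 7, tolerance = 0.02)
  # micro F1 (= accuracy on the balanced set) agrees in expectation
  expect_equal(accuracy(confusion(y, p)), 1 / 7, tolerance = 0.02)
})

test_that("metrics stored in an eval_result are recomputable from its matrix", {
  fx <- make_fixtures(seed = 5, n_subjects = 1, epochs = 1)
  res <- evaluate_model(fx$model, fx$segments)
  expect_equal(res$macro_f1, macro_f1(res$cm))
  expect_equal(res$accuracy, accuracy(res$cm))
  expect_equal(res$macro_precision, macro_precision(res$cm))
  expect_equal(sum(res$cm), n_segments(fx$segments))
  expect_named(glance(res), c("macro_f1", "accuracy", "macro_precision", "n"))
})

test_that("the 70-30 split is stratified, disjoint, and deterministic", {
  ss <- study_segments()
  sp <- split_70_30(ss, seed = 8)
  expect_equal(n_segments(sp$train) + n_segments(sp$test), n_segments(ss))
  # disjoint: every (subject, values) row appears in exactly one side
  key <- function(s) apply(s$x[, 1, 1:6, drop = FALSE], 1,
                           paste, collapse = "|")
  expect_length(intersect(key(sp$train), key(sp$test)), 0)
  # per-class train fraction within [0.65, 0.75]
  frac <- class_counts(sp$train)$n / class_counts(ss)$n
  expect_true(all(frac >= 0.65 & frac <= 0.75))
  sp2 <- split_70_30(ss, seed = 8)
  expect_identical(sp$train$x, sp2$train$x)
  sp3 <- split_70_30(ss, seed = 9)
  expect_false(identical(sp$train$x, sp3$train$x))
  expect_error(split_70_30(subset_segments(ss, 1:5)), "at least 10")
})

test_that("LOSO yields one leak-free fold per subject", {
  co <- generate_cohort(3, default_protocol(cycles = 1), master_seed = 15)
  lr <- loso(co, function() build_bilstm(4),
             train_config(max_epochs = 2L), seed = 3)
  expect_equal(nrow(lr), 3L)
  expect_setequal(lr$subject_id, vapply(co, `[[`, "", "subject_id"))
  for (k in seq_len(3)) {
    res <- lr$result[[k]]
    expect_equal(res$n, lr$n_test[k])
    expect_equal(res$macro_f1, lr$macro_f1[k])
  }
  expect_error(loso(co[1], function() build_bilstm(4)), "at least 2")
})

test_that("subject-increment curves cover every pool size", {
  co <- generate_cohort(2, default_protocol(cycles = 2), master_seed = 16)
  si <- subject_increment(co, function() build_bilstm(4),
                          train_config(max_epochs = 2L), repeats = 2,
                          seed = 5)
  expect_equal(nrow(si), 4L)  # 2 pool sizes x 2 repeats
  expect_setequal(unique(si$n_subjects), 1:2)
  s <- tidy(si)
  expect_equal(nrow(s), 2L)
  expect_true(all(is.finite(s$mean_f1)))
})

test_that("the hyperparameter sweep fills its grid and exports via CSV", {
  ss <- subset_segments(study_segments(),
                        seq_len(min(400, n_segments(study_segments()))))
  sw <- hyperparameter_sweep(function(h) build_bilstm(h),
                             hu_grid = c(2, 4), eps_grid = c(1, 2),
                             segments = ss,
                             config = train_config(max_epochs = 1L),
                             seed = 12)
  expect_equal(nrow(sw), 4L)
  expect_setequal(sw$hidden_units, c(2, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(sw, path, row.names = FALSE)
  rt <- utils::read.csv(path)
  expect_equal(rt$macro_f1, sw$macro_f1, tolerance = 1e-12)
  expect_error(hyperparameter_sweep(function(h) build_bilstm(h),
                                    numeric(0), 1, ss), "empty")
})
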