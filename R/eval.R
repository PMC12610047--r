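# Metrics and the three experimental protocols: stratified 70-30 split,
# subject-increment curves, and leave-one-subject-out validation.

#' Confusion matrix over the seven activity classes
#'
#' @param y_true,y_pred Equal-length vectors of class codes (characters or
#'   activity factors).
#' @return 7 x 7 integer matrix, rows = true class, columns = predicted
#'   class, in [activity_classes()] order.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- activity_factor(y_true); y_pred <- activity_factor(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("length mismatch between `y_true` and `y_pred`", call. = FALSE)
  }
  if (length(y_true) == 0) stop("empty inputs", call. = FALSE)
  cm <- table(true = y_true, pred = y_pred)
  m <- matrix(as.integer(cm), nrow = nrow(cm),
              dimnames = list(true = rownames(cm), pred = colnames(cm)))
  m
}

per_class_prf <- function(cm) {
  tp <- diag(cm)
  pred_n <- colSums(cm); true_n <- rowSums(cm)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(true_n > 0, tp / true_n, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  tibble::tibble(activity = rownames(cm) %||% as.character(seq_len(nrow(cm))),
                 precision = precision,
                 recall = recall, f1 = f1, n_true = as.integer(true_n))
}

#' Macro F1, accuracy, and macro precision from a confusion matrix
#'
#' Macro F1 is the unweighted mean of per-class F1 scores, insensitive to
#' class frequency. A class with zero true and zero predicted instances
#' contributes F1 = 0 and triggers a warning.
#'
#' @param cm Confusion matrix from [confusion()].
#' @return Scalar in `[0, 1]`.
#' @export
macro_f1 <- function(cm) {
  if (sum(cm) == 0) stop("all-zero confusion matrix", call. = FALSE)
  absent <- rowSums(cm) == 0 & colSums(cm) == 0
  if (any(absent)) {
    warning("class(es) absent from truth and predictions score F1 = 0: ",
            paste(rownames(cm)[absent], collapse = ", "))
  }
  mean(per_class_prf(cm)$f1)
}

#' @rdname macro_f1
#' @export
accuracy <- function(cm) sum(diag(cm)) / sum(cm)

#' @rdname macro_f1
#' @export
macro_precision <- function(cm) mean(per_class_prf(cm)$precision)

#' Evaluate a trained model on a test segment set
#'
#' @param model A `har_model`.
#' @param test_set A [segment_set()].
#' @return An `eval_result`: list with the confusion matrix `cm`,
#'   `macro_f1`, `accuracy`, `macro_precision`, and a `per_class` tibble.
#' @export
evaluate_model <- function(model, test_set) {
  pred <- predict(model, test_set)
  cm <- confusion(test_set$y, pred$.pred)
  structure(list(cm = cm, macro_f1 = macro_f1(cm), accuracy = accuracy(cm),
                 macro_precision = macro_precision(cm),
                 per_class = per_class_prf(cm),
                 n = n_segments(test_set)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> n = %d | macro F1 %.3f | accuracy %.3f | macro precision %.3f\n",
              x$n, x$macro_f1, x$accuracy, x$macro_precision))
  invisible(x)
}

#' Stratified 70-30 split
#'
#' Per class, 70% of the segments (rounded) go to training and the rest to
#' testing; deterministic given `seed`. Classes with fewer than 2 segments
#' are kept whole in training with a warning.
#'
#' @param ss A [segment_set()] with at least 10 segments.
#' @param seed Integer seed.
#' @param train_fraction Training share (default 0.7).
#' @return List with disjoint `train` and `test` segment sets.
#' @export
split_70_30 <- function(ss, seed = 1L, train_fraction = 0.7) {
  n <- n_segments(ss)
  if (n < 10L) stop("need at least 10 segments to split", call. = FALSE)
  train_idx <- integer(0)
  withr::with_seed(seed, {
    for (cls in levels(ss$y)) {
      in_cls <- which(ss$y == cls)
      if (length(in_cls) == 0) next
      if (length(in_cls) < 2L) {
        warning("class ", cls, " has < 2 segments; kept whole in train")
        train_idx <- c(train_idx, in_cls)
      } else {
        k <- max(1L, round(train_fraction * length(in_cls)))
        k <- min(k, length(in_cls) - 1L)
        train_idx <- c(train_idx, sample(in_cls, k))
      }
    }
  })
  train_idx <- sort(train_idx)
  list(train = subset_segments(ss, train_idx),
       test = subset_segments(ss, setdiff(seq_len(n), train_idx)))
}

# balance the training portion, train, evaluate: the unit step shared by all
# protocols. `builder` is a zero-argument arch constructor.
run_split_eval <- function(ss, builder, config, seed,
                           balance_cfg = balance_config(seed = seed)) {
  sp <- split_70_30(ss, seed = seed)
  train_bal <- balance_dataset(sp$train, balance_cfg)
  cfg <- config; cfg$seed <- seed
  model <- train_network(train_bal, builder(), cfg)
  evaluate_model(model, sp$test)
}

#' Subject-increment learning curves
#'
#' For `k = 1 .. n_subjects`, pools the first `k` subjects' windows and runs
#' the balance / 70-30 split / train / evaluate cycle `repeats` times with
#' distinct seeds (reshuffling both the split and the initialization),
#' recording macro F1.
#'
#' @param cohort An `mmh_cohort`.
#' @param builder Zero-argument function returning a fresh `arch_spec`.
#' @param config A [train_config()].
#' @param repeats Trainings per subject count (default 3).
#' @param seed Base seed.
#' @return A `subject_increment` tibble: `n_subjects`, `rep`, `macro_f1`,
#'   plus group means/sds via [summary()] or [generics::tidy()].
#' @export
subject_increment <- function(cohort, builder, config = train_config(),
                              repeats = 3L, seed = 1L) {
  if (length(cohort) < 1L) stop("empty cohort", call. = FALSE)
  repeats <- check_count(repeats, "repeats")
  sets <- lapply(cohort, preprocess_session)
  rows <- list()
  for (k in seq_along(cohort)) {
    pooled <- do.call(c, sets[seq_len(k)])
    for (r in seq_len(repeats)) {
      res <- run_split_eval(pooled, builder, config,
                            seed = derive_seed(seed, c(k, r)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n_subjects = k, rep = r, macro_f1 = res$macro_f1,
        accuracy = res$accuracy)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("subject_increment", class(out))
  out
}

#' Leave-one-subject-out validation
#'
#' One fold per subject: fold `k` trains on every other subject's windows
#' (balanced) and tests on subject `k` alone. Subject disjointness is
#' asserted in every fold.
#'
#' @inheritParams subject_increment
#' @return A `loso_result` tibble: `fold`, `subject_id`, `macro_f1`,
#'   `accuracy`, `macro_precision`, `n_test`, with the per-fold
#'   `eval_result`s in the `result` list-column.
#' @export
loso <- function(cohort, builder, config = train_config(), seed = 1L) {
  if (length(cohort) < 2L) stop("LOSO needs at least 2 subjects",
                                call. = FALSE)
  sets <- lapply(cohort, preprocess_session)
  ids <- vapply(cohort, `[[`, "", "subject_id")
  rows <- list()
  for (k in seq_along(cohort)) {
    if (n_segments(sets[[k]]) == 0) {
      stop("subject ", ids[k], " has zero segments", call. = FALSE)
    }
    train_ss <- do.call(c, sets[-k])
    test_ss <- sets[[k]]
    stopifnot(length(intersect(unique(train_ss$subject_id),
                               unique(test_ss$subject_id))) == 0)
    fold_seed <- derive_seed(seed, k)
    train_bal <- balance_dataset(train_ss, balance_config(seed = fold_seed))
    cfg <- config; cfg$seed <- fold_seed
    model <- train_network(train_bal, builder(), cfg)
    res <- evaluate_model(model, test_ss)
    rows[[k]] <- tibble::tibble(fold = k, subject_id = ids[k],
                                macro_f1 = res$macro_f1,
                                accuracy = res$accuracy,
                                macro_precision = res$macro_precision,
                                n_test = res$n, result = list(res))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("loso_result", class(out))
  out
}

#' Epochs x hidden-units grid search
#'
#' Trains one model per (hidden units, epochs) cell on a balanced 70-30
#' split of `segments` and records the test macro F1, the checkerboard of
#' the hyperparameter search.
#'
#' @param builder One-argument function `function(h)` returning an
#'   `arch_spec` with `h` hidden units.
#' @param hu_grid,eps_grid Hidden-unit and epoch grids (non-empty).
#' @param segments Pooled [segment_set()].
#' @param config Base [train_config()] (its `max_epochs` is overridden per
#'   cell).
#' @param seed Base seed (each cell derives its own).
#' @return A `sweep_result` tibble: `hidden_units`, `epochs`, `macro_f1`.
#' @export
hyperparameter_sweep <- function(builder, hu_grid, eps_grid, segments,
                                 config = train_config(), seed = 1L) {
  if (length(hu_grid) == 0 || length(eps_grid) == 0) {
    stop("empty hyperparameter grid", call. = FALSE)
  }
  rows <- list()
  for (h in hu_grid) {
    for (ep in eps_grid) {
      cell_seed <- derive_seed(seed, c(h, ep))
      cfg <- config; cfg$max_epochs <- as.integer(ep); cfg$seed <- cell_seed
      res <- tryCatch(
        run_split_eval(segments, function() builder(h), cfg,
                       seed = cell_seed),
        error = function(e) {
          stop("sweep cell (hu = ", h, ", eps = ", ep, ") failed: ",
               conditionMessage(e), call. = FALSE)
        })
      rows[[length(rows) + 1L]] <- tibble::tibble(
        hidden_units = h, epochs = ep, macro_f1 = res$macro_f1)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_result", class(out))
  out
}
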