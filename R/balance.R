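#' Class-balancing configuration
#'
#' The dominant class (the neutral pose in practice) is down-sampled and
#' minority classes are augmented by replicating their segments with additive
#' white Gaussian noise, until every class holds the target count.
#'
#' @param target_count_rule `"median_class"` (target = median class count) or
#'   `"fixed"` with `fixed_n`.
#' @param fixed_n Target count when `target_count_rule = "fixed"`.
#' @param noise_sd_fraction Augmentation noise standard deviation, expressed
#'   as a fraction of each channel's within-segment standard deviation
#'   (default 0.05).
#' @param seed Integer seed driving selection and noise.
#' @param max_ratio Acceptance bound on the post-balance max/min class-count
#'   ratio.
#' @return A `balance_config` object.
#' @export
balance_config <- function(target_count_rule = c("median_class", "fixed"),
                           fixed_n = NULL, noise_sd_fraction = 0.05,
                           seed = 1L, max_ratio = 1.1) {
  target_count_rule <- match.arg(target_count_rule)
  check_positive(noise_sd_fraction, "noise_sd_fraction")
  if (max_ratio < 1) stop("`max_ratio` must be >= 1", call. = FALSE)
  if (target_count_rule == "fixed") check_count(fixed_n, "fixed_n")
  structure(list(target_count_rule = target_count_rule, fixed_n = fixed_n,
                 noise_sd_fraction = noise_sd_fraction,
                 seed = as.integer(seed), max_ratio = max_ratio),
            class = "balance_config")
}

#' Down-sample one class to a target count
#'
#' Uniform selection without replacement, deterministic given `seed`; all
#' other classes pass through untouched and surviving segments are
#' bit-identical to their originals.
#'
#' @param ss A [segment_set()].
#' @param cls Class code to down-sample.
#' @param target Target count (must not exceed the current count).
#' @param seed Integer seed.
#' @return A `segment_set`.
#' @export
downsample_class <- function(ss, cls, target, seed = 1L) {
  cls <- as.character(activity_factor(cls))
  target <- check_count(target, "target", min = 0L)
  in_cls <- which(ss$y == cls)
  if (target > length(in_cls)) {
    stop("`target` (", target, ") exceeds current count of ", cls, " (",
         length(in_cls), ")", call. = FALSE)
  }
  keep <- withr::with_seed(seed, sort(sample(in_cls, target)))
  subset_segments(ss, sort(c(setdiff(seq_len(n_segments(ss)), in_cls), keep)))
}

#' Augment one class to a target count by noisy replication
#'
#' Source segments are cycled round-robin; each synthetic copy adds i.i.d.
#' Gaussian noise whose per-channel standard deviation is
#' `noise_sd_fraction` times that channel's standard deviation within the
#' source segment. Originals are preserved unmodified; deterministic given
#' the config seed.
#'
#' @param ss A [segment_set()].
#' @param cls Class code to augment.
#' @param target Target count (>= current count, which must be >= 1).
#' @param cfg A [balance_config()].
#' @return A `segment_set` with the synthetic segments appended.
#' @export
augment_class <- function(ss, cls, target, cfg = balance_config()) {
  cls <- as.character(activity_factor(cls))
  target <- check_count(target, "target")
  in_cls <- which(ss$y == cls)
  if (length(in_cls) == 0) {
    stop("cannot augment: class ", cls, " has no segments", call. = FALSE)
  }
  n_new <- target - length(in_cls)
  if (n_new < 0) stop("`target` below current count; use downsample_class",
                      call. = FALSE)
  if (n_new == 0) return(ss)
  src <- in_cls[((seq_len(n_new) - 1L) %% length(in_cls)) + 1L]
  d <- dim(ss$x)
  new_x <- array(0, dim = c(n_new, d[2], d[3]))
  withr::with_seed(derive_seed(cfg$seed, match(cls, activity_classes())), {
    for (j in seq_len(n_new)) {
      seg <- ss$x[src[j], , ]
      ch_sd <- apply(seg, 1L, stats::sd)
      noise <- matrix(stats::rnorm(length(seg)), nrow = d[2]) *
        (cfg$noise_sd_fraction * ch_sd)
      new_x[j, , ] <- seg + noise
    }
  })
  c(ss, segment_set(new_x, rep(cls, n_new), ss$subject_id[src]))
}

#' Balance a segment set across all seven classes
#'
#' Computes the target count from the configured rule, down-samples classes
#' above it and augments classes below it, then shuffles the segment order
#' deterministically. Intended for the training portion only; balancing test
#' data would bias macro-F1.
#'
#' @param ss A [segment_set()]; every class must have at least one segment.
#' @param cfg A [balance_config()].
#' @return A `segment_set` with max/min class-count ratio 1 (<=
#'   `cfg$max_ratio`).
#' @export
balance_dataset <- function(ss, cfg = balance_config()) {
  counts <- table(ss$y)
  missing <- names(counts)[counts == 0]
  if (length(missing) > 0) {
    stop("missing class(es): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  target <- switch(cfg$target_count_rule,
                   median_class = as.integer(round(stats::median(counts))),
                   fixed = cfg$fixed_n)
  out <- ss
  for (cls in activity_classes()) {
    cnt <- sum(out$y == cls)
    if (cnt > target) {
      out <- downsample_class(out, cls, target,
                              seed = derive_seed(cfg$seed, c(7L, match(cls, activity_classes()))))
    } else if (cnt < target) {
      out <- augment_class(out, cls, target, cfg)
    }
  }
  perm <- withr::with_seed(derive_seed(cfg$seed, 999L),
                           sample(n_segments(out)))
  subset_segments(out, perm)
}
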