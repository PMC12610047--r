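# Shared fixtures, generated once per test run and memoized. All fixtures
# are pure functions of fixed seeds.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# two-subject, one-cycle cohort: the small unit-test workhorse
tiny_cohort <- function() {
  memo("tiny_cohort",
       generate_cohort(2, default_protocol(cycles = 1), master_seed = 7))
}

tiny_segments <- function() {
  memo("tiny_segments", preprocess_cohort(tiny_cohort()))
}

# the seed-pinned six-subject study cohort used by the end-to-end
# performance checks (about six minutes of recording per subject)
study_cohort <- function() {
  memo("study_cohort", generate_cohort(6, default_protocol(),
                                       master_seed = 42))
}

study_segments <- function() {
  memo("study_segments", preprocess_cohort(study_cohort()))
}

# nearest-centroid classifier on per-channel window means: the sanity
# ceiling for the separable synthetic construction
nearest_centroid_f1 <- function(train, test) {
  feat <- function(ss) t(apply(ss$x, 1L, function(w) rowMeans(w)))
  tr <- feat(train); te <- feat(test)
  centroids <- sapply(activity_classes(), function(cl) {
    colMeans(tr[train$y == cl, , drop = FALSE])
  })
  pred <- activity_classes()[apply(te, 1L, function(v) {
    which.min(colSums((centroids - v)^2))
  })]
  macro_f1(confusion(test$y, pred))
}
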