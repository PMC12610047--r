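#' Segment sets: the unit flowing through balancing, training, evaluation
#'
#' A segment set holds `n` fixed-shape windows (`channels x win`, canonically
#' 10 x 240), one class label and one subject id per window.
#'
#' @param x Numeric array of dimension `(n, channels, win)`.
#' @param y Activity factor of length `n` (levels [activity_classes()]).
#' @param subject_id Character vector of length `n`.
#' @return An object of class `segment_set` with fields `x`, `y`,
#'   `subject_id`.
#' @export
segment_set <- function(x, y, subject_id) {
  if (length(dim(x)) != 3L) stop("`x` must be an (n, channels, win) array",
                                 call. = FALSE)
  y <- activity_factor(y)
  subject_id <- as.character(subject_id)
  if (dim(x)[1] != length(y) || length(y) != length(subject_id)) {
    stop("inconsistent segment set: nrow(x), length(y), length(subject_id) differ",
         call. = FALSE)
  }
  structure(list(x = x, y = y, subject_id = subject_id),
            class = "segment_set")
}

#' Number of segments in a set
#' @param ss A `segment_set`.
#' @return Integer count.
#' @export
n_segments <- function(ss) dim(ss$x)[1]

#' Per-class segment counts
#'
#' @param ss A `segment_set`.
#' @return Tibble with columns `activity` and `n`, one row per class (zero
#'   rows included).
#' @export
class_counts <- function(ss) {
  tab <- table(ss$y)
  tibble::tibble(activity = names(tab), n = as.integer(tab))
}

#' Subset a segment set by index
#' @param ss A `segment_set`.
#' @param idx Integer or logical index over segments.
#' @return A `segment_set` with the selected segments, in `idx` order.
#' @export
subset_segments <- function(ss, idx) {
  segment_set(ss$x[idx, , , drop = FALSE], ss$y[idx], ss$subject_id[idx])
}

#' @export
c.segment_set <- function(...) {
  parts <- list(...)
  x <- do.call(abind3, lapply(parts, `[[`, "x"))
  y <- activity_factor(unlist(lapply(parts, function(p) as.character(p$y))))
  sid <- unlist(lapply(parts, `[[`, "subject_id"))
  segment_set(x, y, sid)
}

# rbind for 3-d arrays along the first (segment) axis
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], 0L))
  out <- array(0, dim = c(n, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    np <- dim(p)[1]
    if (np > 0) out[at + seq_len(np), , ] <- p
    at <- at + np
  }
  out
}

#' @export
print.segment_set <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<segment_set> %d segments of %d x %d, %d subject(s)\n",
              d[1], d[2], d[3], length(unique(x$subject_id))))
  print(table(x$y))
  invisible(x)
}

#' Flatten segments to a design matrix
#'
#' Each segment's `channels x win` window is flattened row-major by channel
#' (channel 1's 240 samples, then channel 2's, ...) into one row, the input
#' layout of the autoencoder models.
#'
#' @param ss A `segment_set`.
#' @return Numeric matrix `n x (channels * win)`.
#' @export
flatten_segments <- function(ss) {
  d <- dim(ss$x)
  out <- matrix(0, nrow = d[1], ncol = d[2] * d[3])
  for (ch in seq_len(d[2])) {
    out[, (ch - 1L) * d[3] + seq_len(d[3])] <- ss$x[, ch, ]
  }
  out
}

#' Write / read a segment set as plain CSV
#'
#' One row per segment: `subject_id`, `activity`, then the flattened window
#' (`c<channel>_t<sample>` columns). The round trip preserves values to
#' double precision (values are printed with 17 significant digits).
#'
#' @param ss A `segment_set`.
#' @param path CSV file path.
#' @return `write_segments` returns `path` invisibly; `read_segments` returns
#'   the reconstructed `segment_set`.
#' @export
write_segments <- function(ss, path) {
  d <- dim(ss$x)
  flat <- flatten_segments(ss)
  colnames(flat) <- paste0("c", rep(seq_len(d[2]), each = d[3]),
                           "_t", rep(seq_len(d[3]), d[2]))
  df <- data.frame(subject_id = ss$subject_id,
                   activity = as.character(ss$y), flat,
                   check.names = FALSE)
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- df[, 1:2]
  flat <- as.matrix(df[, -(1:2), drop = FALSE])
  nm <- colnames(flat)
  ch <- as.integer(sub("^c(\\d+)_t\\d+$", "\\1", nm))
  n_ch <- max(ch)
  win <- ncol(flat) / n_ch
  x <- array(0, dim = c(nrow(flat), n_ch, win))
  for (k in seq_len(n_ch)) {
    x[, k, ] <- flat[, ch == k, drop = FALSE]
  }
  segment_set(x, meta$activity, meta$subject_id)
}

#' Write / read a raw session as plain CSV + YAML metadata
#'
#' `write_session` writes `<dir>/kin.csv` (one column per kinematic channel
#' plus the label stream), `<dir>/semg.csv`, and `<dir>/meta.yml` (subject
#' id, rates, channel names). `read_session` reconstructs the session.
#'
#' @param session An `mmh_session`.
#' @param dir Directory (created if missing).
#' @return `write_session` returns `dir` invisibly; `read_session` the
#'   session.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kin <- as.data.frame(t(session$kin))
  names(kin) <- kinematic_channel_names()
  kin$label <- as.character(session$labels)
  utils::write.csv(format(kin, digits = 17, scientific = TRUE, trim = TRUE),
                   file.path(dir, "kin.csv"), row.names = FALSE, quote = FALSE)
  semg <- as.data.frame(t(session$semg))
  names(semg) <- semg_channel_names()
  utils::write.csv(format(semg, digits = 17, scientific = TRUE, trim = TRUE),
                   file.path(dir, "semg.csv"), row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(subject_id = session$subject_id,
                        kin_rate_hz = session$kin_rate_hz,
                        semg_rate_hz = session$semg_rate_hz,
                        mvc = session$params$mvc,
                        channel_names = channel_names()),
                   file.path(dir, "meta.yml"))
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yml"))
  kin <- utils::read.csv(file.path(dir, "kin.csv"))
  semg <- utils::read.csv(file.path(dir, "semg.csv"))
  labels <- activity_factor(kin$label)
  kin$label <- NULL
  structure(list(subject_id = meta$subject_id,
                 kin = t(as.matrix(kin)),
                 semg = t(as.matrix(semg)),
                 kin_rate_hz = as.integer(meta$kin_rate_hz),
                 semg_rate_hz = as.integer(meta$semg_rate_hz),
                 labels = labels,
                 channel_names = meta$channel_names,
                 protocol = NULL,
                 params = subject_params(subject_id = meta$subject_id,
                                         mvc = meta$mvc)),
            class = "mmh_session")
}
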