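#' sEMG conditioning: 50 Hz notch filter
#'
#' Zero-phase band-stop (second-order Butterworth design, applied
#' forward-backward) centred on the mains frequency. Attenuates a probe tone
#' at `f0` by more than 20 dB while leaving the passband essentially
#' untouched; zero-phase application preserves label alignment.
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz).
#' @param f0 Notch centre frequency (Hz), default 50.
#' @param width_hz Half-width of the stop band (Hz).
#' @return Filtered series, same length as `x`.
#' @export
notch_filter <- function(x, fs, f0 = 50, width_hz = 2) {
  check_positive(fs, "fs")
  if (f0 <= 0 || f0 >= fs / 2) {
    stop("Nyquist violation: `f0` must lie in (0, fs/2)", call. = FALSE)
  }
  bf <- signal::butter(2, c(f0 - width_hz, f0 + width_hz) / (fs / 2),
                       type = "stop")
  as.numeric(signal::filtfilt(bf$b, bf$a, as.numeric(x)))
}

#' sEMG conditioning: Butterworth band-pass
#'
#' Zero-phase Butterworth band-pass (default 20-500 Hz, order 4), the
#' standard sEMG conditioning band. Applied forward-backward, so the
#' effective attenuation is twice the one-pass design and the group delay is
#' zero.
#'
#' @inheritParams notch_filter
#' @param lo,hi Band edges (Hz).
#' @param order Butterworth design order (per pass).
#' @return Filtered series, same length as `x`.
#' @export
bandpass_butterworth <- function(x, fs, lo = 20, hi = 500, order = 4) {
  check_positive(fs, "fs")
  if (!(lo > 0 && lo < hi)) stop("need 0 < lo < hi", call. = FALSE)
  if (hi >= fs / 2) {
    stop("Nyquist violation: `hi` must be < fs/2", call. = FALSE)
  }
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf$b, bf$a, as.numeric(x)))
}

#' sEMG conditioning: full-wave rectification
#'
#' @param x Numeric series.
#' @return `abs(x)`.
#' @export
rectify <- function(x) abs(x)

#' sEMG conditioning: MVC normalization
#'
#' Scales the rectified sEMG by the subject-specific maximum voluntary
#' contraction so amplitudes are comparable across subjects.
#'
#' @param x Numeric series.
#' @param mvc Positive MVC amplitude in the units of `x`.
#' @return `x / mvc`.
#' @export
mvc_normalize <- function(x, mvc) {
  check_positive(mvc, "mvc")
  x / mvc
}

#' sEMG conditioning: sliding RMS envelope
#'
#' Centred sliding-window root-mean-square with shrink-to-valid edges: each
#' output sample is the RMS of the input over the part of its window that
#' falls inside the series, so the output has the same length as the input
#' and no padding values are fabricated. Computed with a cumulative-sum of
#' squares, numerically equal (to ~1e-12 relative) to the per-sample
#' definition.
#'
#' @param x Numeric series (non-empty).
#' @param fs Sampling rate (Hz).
#' @param window_ms Window length in milliseconds (default 250).
#' @return RMS envelope, same length as `x`.
#' @export
rms_envelope <- function(x, fs, window_ms = 250) {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  check_positive(fs, "fs")
  w <- as.integer(round(window_ms * fs / 1000))
  if (w < 1L) stop("window shorter than one sample", call. = FALSE)
  n <- length(x)
  half_lo <- (w - 1L) %/% 2L          # samples before the centre
  half_hi <- w - 1L - half_lo         # samples after the centre
  cs <- c(0, cumsum(as.numeric(x)^2))
  idx <- seq_len(n)
  lo <- pmax(idx - half_lo, 1L)
  hi <- pmin(idx + half_hi, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Resample a series onto the 240 Hz kinematic clock
#'
#' Linear interpolation of the (already low-passed) sEMG envelope onto the
#' kinematic sample grid. Intended for smooth envelopes only - the 250 ms RMS
#' envelope is band-limited far below the 120 Hz Nyquist of the target rate,
#' so interpolation is an adequate rate converter. Duration is preserved
#' within one output sample; a constant maps to a constant.
#'
#' @param x Numeric series at `fs_in` Hz.
#' @param fs_in Input sampling rate; must be >= 240.
#' @return Series at 240 Hz spanning the same duration.
#' @export
resample_to_240 <- function(x, fs_in) {
  check_positive(fs_in, "fs_in")
  if (fs_in < KIN_RATE_HZ) {
    stop("upsampling not supported: `fs_in` must be >= 240", call. = FALSE)
  }
  if (fs_in == KIN_RATE_HZ) return(as.numeric(x))
  n_in <- length(x)
  n_out <- as.integer(round(n_in * KIN_RATE_HZ / fs_in))
  t_in <- (seq_len(n_in) - 1) / fs_in
  t_out <- (seq_len(n_out) - 1) / KIN_RATE_HZ
  stats::approx(t_in, as.numeric(x), xout = pmin(t_out, t_in[n_in]),
                rule = 2)$y
}

#' Full sEMG conditioning chain for a session
#'
#' Applies, per raw sEMG channel: 50 Hz notch, 20-500 Hz Butterworth
#' band-pass, rectification, MVC normalization, 250 ms RMS envelope - all at
#' the native sEMG rate - then resamples the envelope onto the 240 Hz
#' kinematic clock. Processing precedes alignment because the conditioning
#' band (up to 500 Hz) is unrepresentable at 240 Hz.
#'
#' @param session An `mmh_session`.
#' @param mvc MVC amplitude; defaults to the session's simulated MVC.
#' @return 2 x T matrix of MVC-normalized envelopes at 240 Hz, T matching the
#'   kinematic sample count.
#' @export
process_semg <- function(session, mvc = session$params$mvc) {
  fs <- session$semg_rate_hz
  t_kin <- ncol(session$kin)
  out <- matrix(0, nrow = 2L, ncol = t_kin)
  for (ch in 1:2) {
    y <- session$semg[ch, ]
    y <- notch_filter(y, fs)
    y <- bandpass_butterworth(y, fs)
    y <- rectify(y)
    y <- mvc_normalize(y, mvc)
    y <- rms_envelope(y, fs)
    y <- resample_to_240(y, fs)
    # per-bout rounding can leave the envelope one sample short/long of the
    # kinematic clock; align by truncation / edge-hold
    if (length(y) >= t_kin) out[ch, ] <- y[seq_len(t_kin)]
    else out[ch, ] <- c(y, rep(y[length(y)], t_kin - length(y)))
  }
  out
}

#' Early fusion of kinematic and processed sEMG channels
#'
#' Vertically stacks the eight kinematic channels and the two sEMG envelopes
#' into the canonical 10 x T matrix all networks consume; labels pass through
#' unchanged.
#'
#' @param session An `mmh_session`.
#' @param semg_processed 2 x T matrix at 240 Hz (from [process_semg()]);
#'   computed from the session if omitted.
#' @return A `fused_series`: list with `data` (10 x T), `labels` (factor,
#'   length T), `subject_id`, `channel_names`.
#' @export
fuse_channels <- function(session, semg_processed = NULL) {
  if (is.null(semg_processed)) semg_processed <- process_semg(session)
  if (ncol(semg_processed) != ncol(session$kin)) {
    stop("alignment error: processed sEMG length ", ncol(semg_processed),
         " != kinematic length ", ncol(session$kin), call. = FALSE)
  }
  if (nrow(semg_processed) != 2L) {
    stop("alignment error: expected 2 processed sEMG channels", call. = FALSE)
  }
  data <- rbind(session$kin, semg_processed)
  rownames(data) <- channel_names()
  structure(list(data = data, labels = session$labels,
                 subject_id = session$subject_id,
                 channel_names = channel_names()),
            class = "fused_series")
}

#' Segment a fused series into fixed one-second windows
#'
#' Non-overlapping sliding windows (default 240 samples = 1 s, stride 240).
#' Each window's label is the majority label inside it, ties broken toward
#' the label of the window's centre sample; any trailing remainder shorter
#' than one window is discarded.
#'
#' @param fused A `fused_series`.
#' @param win Window length in samples.
#' @param stride Stride in samples.
#' @return A [segment_set()] with `floor((T - win)/stride) + 1` segments.
#' @export
segment_windows <- function(fused, win = 240L, stride = 240L) {
  win <- check_count(win, "win"); stride <- check_count(stride, "stride")
  tt <- ncol(fused$data)
  if (tt < win) {
    warning("series shorter than one window: empty segment set")
    return(segment_set(array(0, dim = c(0L, nrow(fused$data), win)),
                       activity_factor(character(0)), character(0)))
  }
  n_seg <- (tt - win) %/% stride + 1L
  x <- array(0, dim = c(n_seg, nrow(fused$data), win))
  y <- character(n_seg)
  lab <- as.character(fused$labels)
  for (k in seq_len(n_seg)) {
    i0 <- (k - 1L) * stride
    x[k, , ] <- fused$data[, i0 + seq_len(win)]
    wl <- lab[i0 + seq_len(win)]
    tab <- table(wl)
    top <- names(tab)[tab == max(tab)]
    y[k] <- if (length(top) == 1L) top else {
      centre <- wl[(win + 1L) %/% 2L]
      if (centre %in% top) centre else top[1L]
    }
  }
  segment_set(x, activity_factor(y), rep(fused$subject_id, n_seg))
}

#' Preprocess a session end to end
#'
#' Conditioning chain, early fusion, and window segmentation in one call.
#'
#' @param session An `mmh_session`.
#' @inheritParams segment_windows
#' @return A [segment_set()].
#' @export
preprocess_session <- function(session, win = 240L, stride = 240L) {
  segment_windows(fuse_channels(session), win = win, stride = stride)
}

#' Preprocess every session of a cohort
#'
#' @param cohort An `mmh_cohort`.
#' @inheritParams segment_windows
#' @return A single [segment_set()] pooling all subjects' windows.
#' @export
preprocess_cohort <- function(cohort, win = 240L, stride = 240L) {
  sets <- lapply(cohort, preprocess_session, win = win, stride = stride)
  do.call(c, sets)
}
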