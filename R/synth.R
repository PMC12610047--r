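#' Build an activity protocol
#'
#' A protocol is the scripted sequence of activities one subject performs:
#' one row per activity bout with its duration and the handled load. It is the
#' input script for [generate_session()].
#'
#' @param activity Character vector of class codes (see [activity_classes()]).
#' @param duration_s Positive durations in seconds, recycled to length of
#'   `activity`.
#' @param load_kg Non-negative handled loads in kg, recycled likewise.
#' @return A tibble with columns `activity` (factor), `duration_s`, `load_kg`.
#' @export
#' @examples
#' mmh_protocol(c("N", "LF", "K"), c(4, 2, 3), c(0, 10, 10))
mmh_protocol <- function(activity, duration_s, load_kg = 0) {
  if (length(activity) == 0) stop("protocol must be non-empty", call. = FALSE)
  activity <- activity_factor(activity)
  duration_s <- rep_len(as.numeric(duration_s), length(activity))
  load_kg <- rep_len(as.numeric(load_kg), length(activity))
  if (any(!is.finite(duration_s)) || any(duration_s <= 0)) {
    stop("invalid protocol: all durations must be > 0", call. = FALSE)
  }
  if (any(!is.finite(load_kg)) || any(load_kg < 0)) {
    stop("invalid protocol: loads must be >= 0", call. = FALSE)
  }
  tibble::tibble(activity = activity, duration_s = duration_s,
                 load_kg = load_kg)
}

#' Default lift-carry-place protocol
#'
#' A handling cycle (N-pose, lift from floor, keep, carry, place on table,
#' N-pose, lift from table, carry, place on floor, N-pose) repeated `cycles`
#' times. One cycle lasts 29 s; the default 12 cycles give a session of
#' about six minutes, a typical length for a laboratory handling series.
#' The neutral pose dominates the label stream, mirroring the natural
#' imbalance of handling recordings where the subject stands idle between
#' bouts.
#'
#' @param load_kg Load handled during the non-neutral bouts (kg).
#' @param cycles Number of repetitions of the cycle.
#' @return A protocol tibble (see [mmh_protocol()]).
#' @export
default_protocol <- function(load_kg = 10, cycles = 12) {
  cycles <- check_count(cycles, "cycles")
  one <- mmh_protocol(
    activity   = c("N", "LF", "K", "W", "PT", "N", "LT", "W", "PF", "N"),
    duration_s = c(4, 2, 3, 4, 2, 3, 2, 3, 2, 4),
    load_kg    = c(0, load_kg, load_kg, load_kg, load_kg, 0,
                   load_kg, load_kg, load_kg, 0)
  )
  dplyr::bind_rows(rep(list(one), cycles))
}

#' Per-subject simulation parameters
#'
#' Captures inter-subject variability: a kinematic amplitude gain, an sEMG
#' gain, the simulated maximum voluntary contraction (MVC, same units as the
#' raw sEMG), additive sensor-noise standard deviation, and the subject's RNG
#' seed.
#'
#' @param subject_id Subject identifier string.
#' @param amplitude_scale Positive kinematic gain.
#' @param semg_gain Positive sEMG gain.
#' @param mvc Positive simulated MVC amplitude.
#' @param noise_sd Non-negative additive noise standard deviation (applied to
#'   kinematic channels directly and, scaled by `mvc`, to the raw sEMG).
#' @param seed Integer RNG seed for this subject's session.
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(subject_id = "S01", amplitude_scale = 1,
                           semg_gain = 1, mvc = 1, noise_sd = 0.02,
                           seed = 1L) {
  check_positive(amplitude_scale, "amplitude_scale")
  check_positive(semg_gain, "semg_gain")
  check_positive(mvc, "mvc")
  check_non_negative(noise_sd, "noise_sd")
  structure(list(subject_id = as.character(subject_id),
                 amplitude_scale = amplitude_scale, semg_gain = semg_gain,
                 mvc = mvc, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "subject_params")
}

# Class-specific kinematic motif, returned as an 8 x n matrix of offsets from
# the standing baseline. `u` is the within-bout phase in [0, 1]. Shapes are
# half-cosine excursions for transient bouts, sustained ramps for held bouts,
# and an oscillatory gait pattern for carrying; amplitudes are in the natural
# units of each channel (rad, m, m/s, m/s^2).
class_motif <- function(cls, n, amplitude_scale, fs = KIN_RATE_HZ) {
  u <- if (n == 1L) 0.5 else seq(0, 1, length.out = n)
  bump <- 0.5 * (1 - cos(2 * pi * u))              # 0 -> 1 -> 0
  hold <- pmin(u / 0.15, 1)                        # ramp then sustain
  t_s <- (seq_len(n) - 1) / fs
  gait <- abs(sin(2 * pi * 1.8 * t_s))             # ~1.8 Hz step pattern
  m <- matrix(0, nrow = 8L, ncol = n)
  a <- amplitude_scale
  switch(cls,
    N = NULL,
    LF = {
      m[1, ] <- 1.00 * a * bump                    # chest
      m[2, ] <- 0.15 * a * bump                    # shoulder
      m[4, ] <- 1.50 * a * bump                    # knee
      m[5, ] <- 0.25 * a * bump                    # hand front position
      m[6, ] <- 0.80 * a * sin(2 * pi * u)         # hand front acceleration
      m[8, ] <- -0.45 * a * bump                   # pelvis vertical drop
    },
    K = {
      m[2, ] <- 0.30 * a * hold
      m[3, ] <- 0.90 * a * hold                    # elbow held flexed
      m[5, ] <- 0.20 * a * hold
    },
    PT = {
      m[2, ] <- 0.80 * a * bump
      m[3, ] <- 0.50 * a * bump
      m[5, ] <- 0.45 * a * bump
      m[8, ] <- 0.05 * a * bump
    },
    LT = {
      m[1, ] <- 0.25 * a * bump
      m[3, ] <- 0.80 * a * bump
      m[5, ] <- 0.15 * a * bump
      m[6, ] <- -0.60 * a * sin(2 * pi * u)
    },
    W = {
      m[4, ] <- 0.30 * a * gait
      m[6, ] <- 0.50 * a * sin(2 * pi * 1.8 * t_s)
      m[7, ] <- 1.20 * a * hold                    # sustained transversal velocity
    },
    PF = {
      m[1, ] <- 0.85 * a * bump
      m[2, ] <- 0.35 * a * bump
      m[4, ] <- 1.40 * a * bump
      m[5, ] <- -0.10 * a * bump
      m[6, ] <- -0.80 * a * sin(2 * pi * u)
      m[8, ] <- -0.42 * a * bump
    },
    stop("unknown class symbol: ", cls, call. = FALSE)
  )
  m
}

# Standing baseline per kinematic channel (rad / m / m/s / m).
KIN_BASELINE <- c(0.10, 0.10, 0.20, 0.10, 0.30, 0.00, 0.00, 0.95)

# Per-class muscular effort level (dimensionless, before load and gain
# scaling) and the within-bout envelope shape of the sEMG burst.
semg_effort_level <- function(cls) {
  switch(cls, N = 0.05, LF = 0.50, K = 0.70, PT = 0.45, LT = 0.50,
         W = 0.35, PF = 0.40)
}

semg_envelope_shape <- function(cls, u) {
  switch(cls,
    N  = rep(1, length(u)),
    LF = 0.3 + 0.7 * u,                       # effort rises as load is taken
    K  = rep(1, length(u)),
    PT = 1 - 0.6 * u,                         # effort released onto table
    LT = 0.4 + 0.6 * u,
    W  = 0.85 + 0.15 * abs(sin(2 * pi * 3 * u)),
    PF = 1 - 0.7 * u)
}

#' Generate one synthetic labeled session
#'
#' Simulates one subject performing a protocol: eight kinematic channels at
#' 240 Hz carrying class-specific motion motifs, and two raw sEMG channels at
#' `semg_rate_hz` built as band-limited stochastic carriers (20-500 Hz)
#' amplitude-modulated by a muscular-effort envelope that grows monotonically
#' with the handled load. The per-sample label stream is aligned to the
#' kinematic clock. Identical arguments (including the seed inside `params`)
#' reproduce the session bit-for-bit.
#'
#' @param protocol A protocol tibble from [mmh_protocol()].
#' @param params A [subject_params()] object.
#' @param semg_rate_hz Raw sEMG sampling rate (Hz); must be at least 1000 so
#'   the 20-500 Hz conditioning band is realizable.
#' @return An `mmh_session`: list with `kin` (8 x T matrix, 240 Hz), `semg`
#'   (2 x T' matrix), `labels` (factor, length T), rates, `subject_id`,
#'   `channel_names`, and the generating `protocol`/`params`.
#' @export
#' @examples
#' s <- generate_session(mmh_protocol("N", 5), subject_params(seed = 7))
#' length(s$labels)  # 5 s x 240 Hz = 1200
generate_session <- function(protocol, params = subject_params(),
                             semg_rate_hz = SEMG_RATE_HZ) {
  if (!inherits(params, "subject_params")) {
    stop("`params` must be a subject_params object", call. = FALSE)
  }
  protocol <- mmh_protocol(protocol$activity, protocol$duration_s,
                           protocol$load_kg)
  if (semg_rate_hz < 1000) {
    stop("`semg_rate_hz` must be >= 1000 Hz", call. = FALSE)
  }
  n_kin <- as.integer(round(protocol$duration_s * KIN_RATE_HZ))
  n_semg <- as.integer(round(protocol$duration_s * semg_rate_hz))
  total_kin <- sum(n_kin)
  total_semg <- sum(n_semg)

  withr::with_seed(params$seed, {
    kin <- matrix(0, nrow = 8L, ncol = total_kin)
    semg <- matrix(0, nrow = 2L, ncol = total_semg)
    labels <- character(total_kin)
    pos_k <- 0L; pos_e <- 0L
    muscle_gain <- c(1.0, 0.8)  # biceps brachii, brachioradialis
    for (i in seq_len(nrow(protocol))) {
      cls <- as.character(protocol$activity[i])
      nk <- n_kin[i]; ne <- n_semg[i]
      labels[pos_k + seq_len(nk)] <- cls
      kin[, pos_k + seq_len(nk)] <-
        KIN_BASELINE + class_motif(cls, nk, params$amplitude_scale)
      u <- if (ne == 1L) 0.5 else seq(0, 1, length.out = ne)
      level <- params$semg_gain *
        (semg_effort_level(cls) + 0.04 * protocol$load_kg[i]) *
        semg_envelope_shape(cls, u)
      for (ch in 1:2) {
        carrier <- bandlimited_noise(ne, semg_rate_hz)
        semg[ch, pos_e + seq_len(ne)] <-
          0.4 * params$mvc * muscle_gain[ch] * level * carrier
      }
      pos_k <- pos_k + nk; pos_e <- pos_e + ne
    }
    if (params$noise_sd > 0) {
      kin <- kin + matrix(stats::rnorm(length(kin), sd = params$noise_sd),
                          nrow = 8L)
      semg <- semg + matrix(stats::rnorm(length(semg),
                                         sd = params$noise_sd * params$mvc),
                            nrow = 2L)
    }
    structure(list(subject_id = params$subject_id, kin = kin, semg = semg,
                   kin_rate_hz = KIN_RATE_HZ,
                   semg_rate_hz = as.integer(semg_rate_hz),
                   labels = activity_factor(labels),
                   channel_names = channel_names(),
                   protocol = protocol, params = params),
              class = "mmh_session")
  })
}

# Unit-variance white noise band-limited to the 20-500 Hz sEMG band.
bandlimited_noise <- function(n, fs) {
  x <- stats::rnorm(n)
  if (n < 24L) return(x)  # too short to filter meaningfully
  bf <- signal::butter(2, c(20, 500) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf$b, bf$a, x)
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

#' @export
print.mmh_session <- function(x, ...) {
  cat(sprintf("<mmh_session> subject %s: %d kin samples @ %d Hz, %d sEMG samples @ %d Hz\n",
              x$subject_id, ncol(x$kin), x$kin_rate_hz, ncol(x$semg),
              x$semg_rate_hz))
  print(table(x$labels))
  invisible(x)
}

#' Generate a synthetic cohort of subjects
#'
#' Draws per-subject parameters deterministically from `master_seed`
#' (amplitude scale, sEMG gain and MVC uniform on documented ranges; load
#' jittered per subject) and generates one session per subject. Neutral-pose
#' bouts are stretched, identically for every subject, until the N class
#' holds at least `imbalance_n_fraction` of all samples, reproducing the
#' dominant-rest-class imbalance of real handling recordings.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param protocol_template Protocol tibble used for every subject.
#' @param master_seed Integer seed governing all randomness.
#' @param imbalance_n_fraction Minimum cohort-wide fraction of N-pose samples,
#'   in (0, 1).
#' @param noise_sd Per-subject sensor noise standard deviation.
#' @return An `mmh_cohort`: list of `mmh_session` objects with distinct
#'   subject ids.
#' @export
generate_cohort <- function(n_subjects, protocol_template = default_protocol(),
                            master_seed = 1L, imbalance_n_fraction = 0.4,
                            noise_sd = 0.02) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  if (imbalance_n_fraction <= 0 || imbalance_n_fraction >= 1) {
    stop("`imbalance_n_fraction` must be in (0, 1)", call. = FALSE)
  }
  proto <- mmh_protocol(protocol_template$activity,
                        protocol_template$duration_s,
                        protocol_template$load_kg)
  is_n <- proto$activity == "N"
  if (!any(is_n)) stop("protocol template must contain N-pose bouts",
                       call. = FALSE)
  n_dur <- sum(proto$duration_s[is_n])
  other <- sum(proto$duration_s[!is_n])
  f <- imbalance_n_fraction
  need <- f * other / ((1 - f) * n_dur)
  # stretch idle bouts to whole seconds: ceiling guarantees the requested
  # fraction and keeps bout boundaries aligned with the 1 s window grid
  if (need > 1) {
    proto$duration_s[is_n] <- ceiling(proto$duration_s[is_n] * need)
  }

  sessions <- lapply(seq_len(n_subjects), function(i) {
    seed_i <- derive_seed(master_seed, i)
    draws <- withr::with_seed(derive_seed(master_seed, c(i, 101L)),
                              stats::runif(4))
    p <- subject_params(
      subject_id = sprintf("S%02d", i),
      amplitude_scale = 0.85 + 0.30 * draws[1],
      semg_gain = 0.80 + 0.40 * draws[2],
      mvc = 0.80 + 0.40 * draws[3],
      noise_sd = noise_sd,
      seed = seed_i
    )
    proto_i <- proto
    proto_i$load_kg <- proto$load_kg * (0.8 + 0.4 * draws[4])
    generate_session(proto_i, p)
  })
  structure(sessions, class = "mmh_cohort")
}

#' @export
print.mmh_cohort <- function(x, ...) {
  cat(sprintf("<mmh_cohort> %d subjects: %s\n", length(x),
              paste(vapply(x, `[[`, "", "subject_id"), collapse = ", ")))
  invisible(x)
}

#' Label census of a cohort
#'
#' @param cohort An `mmh_cohort`.
#' @return Tibble with per-class sample counts and fractions across the
#'   cohort's label streams.
#' @export
cohort_label_census <- function(cohort) {
  tab <- table(factor(unlist(lapply(cohort, function(s) as.character(s$labels))),
                      levels = activity_classes()))
  tibble::tibble(activity = names(tab), n = as.integer(tab),
                 fraction = as.numeric(tab) / sum(tab))
}
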