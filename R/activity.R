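#' Activity classes of the manual material handling taxonomy
#'
#' Seven activity classes are recognised: the neutral standing pose and six
#' load-handling phases. The integer encoding (0-based) is fixed here and used
#' everywhere else in the package (label streams, confusion matrices, on-disk
#' label columns).
#'
#' | code | integer | meaning                 |
#' |------|---------|-------------------------|
#' | N    | 0       | N-pose (neutral stand)  |
#' | LF   | 1       | Lifting from the Floor  |
#' | K    | 2       | Keeping lifted          |
#' | PT   | 3       | Placing on the Table    |
#' | LT   | 4       | Lifting from the Table  |
#' | W    | 5       | Carrying (walking)      |
#' | PF   | 6       | Placing on the Floor    |
#'
#' @return Character vector of the seven class codes, in encoding order.
#' @export
#' @examples
#' activity_classes()
activity_classes <- function() {
  c("N", "LF", "K", "PT", "LT", "W", "PF")
}

#' Coerce a vector of class codes to the canonical activity factor
#'
#' @param x Character vector (or factor) of class codes.
#' @return Factor with levels `activity_classes()`.
#' @export
activity_factor <- function(x) {
  lv <- activity_classes()
  x <- as.character(x)
  bad <- setdiff(unique(x), lv)
  if (length(bad) > 0) {
    stop("unknown activity class symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(x, levels = lv)
}

#' Canonical fused channel order
#'
#' The ten channels every network consumes, in the fixed early-fusion row
#' order: eight kinematic channels followed by the two sEMG RMS envelopes.
#' Kinematic angles are in radians, positions in metres, the pelvis
#' transversal-plane velocity in m/s, the hand front acceleration in m/s^2;
#' sEMG envelopes are MVC-normalized (dimensionless).
#'
#' @return Character vector of length 10.
#' @export
channel_names <- function() {
  c("chest_flexion", "shoulder_flexion", "elbow_flexion", "knee_flexion",
    "hand_front_position", "hand_front_acceleration",
    "pelvis_transversal_velocity", "pelvis_vertical_position",
    "semg_biceps_brachii", "semg_brachioradialis")
}

#' @rdname channel_names
#' @export
kinematic_channel_names <- function() channel_names()[1:8]

#' @rdname channel_names
#' @export
semg_channel_names <- function() channel_names()[9:10]

# Kinematic sampling rate shared by the fused representation (Hz).
KIN_RATE_HZ <- 240L
# Default synthetic raw sEMG rate (Hz); must exceed 2 * 500 Hz so the
# 20-500 Hz band-pass is realizable.
SEMG_RATE_HZ <- 2000L
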