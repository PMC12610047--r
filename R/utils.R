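# Internal helpers: argument checks and deterministic seed fan-out.

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  invisible(x)
}

check_positive <- function(x, name) {
  stop_if_not_scalar_number(x, name)
  if (x <= 0) stop("`", name, "` must be > 0", call. = FALSE)
  invisible(x)
}

check_non_negative <- function(x, name) {
  stop_if_not_scalar_number(x, name)
  if (x < 0) stop("`", name, "` must be >= 0", call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  stop_if_not_scalar_number(x, name)
  if (x < min || x != as.integer(x)) {
    stop("`", name, "` must be an integer >= ", min, call. = FALSE)
  }
  invisible(as.integer(x))
}

# Deterministic seed derivation: mixes a parent seed with a stream index into
# a reproducible child seed below 2^31. Splitmix-style integer hash done in
# double precision (exact for < 2^53).
derive_seed <- function(seed, stream) {
  z <- (abs(as.numeric(seed)) %% 2147483647) + 1
  for (s in as.numeric(stream)) {
    z <- (z * 48271 + (abs(s) %% 2147483647) + 1) %% 2147483647
    z <- (z * 16807) %% 2147483647
  }
  as.integer(z %% 2147483629 + 1)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax with max-shift stabilisation.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}
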