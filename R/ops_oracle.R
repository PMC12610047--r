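# Instrumented reference forward pass: a straight-line scalar
# implementation of every layer that increments an operation counter at each
# multiplication, addition and accumulated product it executes. It pins the
# analytic MAC/MA convention of count_mac()/count_ma() and doubles as a
# value-level reference for the batched runtime. Intended for tiny shapes.

#' Instrumented reference forward pass (operation-counting oracle)
#'
#' Runs one input through the architecture using scalar loops, counting
#' every executed multiplication, addition and accumulated product. The
#' resulting counts define the package's MAC/MA convention; the analytic
#' [count_mac()]/[count_ma()] must reproduce them exactly (a pinned
#' invariant of the test suite). Transcendental evaluations and reciprocal
#' square roots are not counted; divisions count as multiplications.
#'
#' @param spec An `arch_spec` (tiny shapes; this is O(operations) R code).
#' @param params Parameter store from [init_params()].
#' @param x Single input, `channels x win` matrix (defaults to a seeded
#'   standard-normal input).
#' @return List with `mult`, `add`, `mac`, `ma` counts and `out`, the final
#'   activation computed by the reference pass.
#' @export
ops_oracle <- function(spec, params = init_params(spec, seed = 1L),
                       x = NULL) {
  if (is.null(x)) {
    x <- withr::with_seed(1L,
      matrix(stats::rnorm(prod(spec$input_shape)), spec$input_shape[1]))
  }
  ct <- new.env(parent = emptyenv())
  ct$mult <- 0; ct$add <- 0; ct$mac <- 0
  a <- x                                    # seq state: d x T matrix
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]; p <- params[[i]]
    a <- switch(ly$kind,
      sequence_input = a,
      seq_fold = array(a, dim = c(dim(a), 1L)),
      seq_unfold = a,
      conv2d = oracle_conv(a, p, ly$params, ct),
      instance_norm = oracle_instnorm(a, p, ct),
      relu = pmax(a, 0),
      flatten = {
        if (length(dim(a)) == 3L) {
          d <- dim(a)
          if (isTRUE(ly$params$keep_time)) {
            matrix(aperm(a, c(1, 3, 2)), nrow = d[1] * d[3])
          } else {
            matrix(as.vector(a), ncol = 1L)
          }
        } else {
          if (isTRUE(ly$params$keep_time)) a
          else matrix(as.vector(a), ncol = 1L)
        }
      },
      bilstm = oracle_rnn("bilstm", a, p, ct),
      lstm = oracle_rnn("lstm", a, p, ct),
      gru = oracle_rnn("gru", a, p, ct),
      dense = oracle_dense(a, p, ct),
      encoder_dense = sigmoid(oracle_dense(a, p, ct)),
      softmax = oracle_softmax(a, ct),
      classification_output = a,
      stop("unsupported layer kind: ", ly$kind, call. = FALSE))
    # recurrent layers honour return_sequence; for the bidirectional layer
    # "last" means each direction's final state (backward's is at t = 1)
    if (ly$kind %in% c("bilstm", "lstm", "gru") &&
        !isTRUE(ly$params$return_sequence)) {
      if (ly$kind == "bilstm") {
        h2 <- nrow(a) / 2L
        a <- matrix(c(a[seq_len(h2), ncol(a)],
                      a[h2 + seq_len(h2), 1L]), ncol = 1L)
      } else {
        a <- a[, ncol(a), drop = FALSE]
      }
    }
  }
  list(mult = ct$mult, add = ct$add, mac = ct$mac, ma = ct$mult + ct$add,
       out = a)
}

oracle_dense <- function(x, p, ct) {
  d <- nrow(x); t_len <- ncol(x); o <- ncol(p$W)
  out <- matrix(0, o, t_len)
  for (t in seq_len(t_len)) {
    for (j in seq_len(o)) {
      acc <- p$b[j]
      for (k in seq_len(d)) {
        acc <- acc + x[k, t] * p$W[k, j]
        ct$mult <- ct$mult + 1; ct$add <- ct$add + 1; ct$mac <- ct$mac + 1
      }
      out[j, t] <- acc
    }
  }
  out
}

oracle_conv <- function(x, p, lp, ct) {
  d <- dim(x); h <- d[1]; w <- d[2]; cin <- d[3]
  kh <- lp$kernel[1]; kw <- lp$kernel[2]
  sh <- lp$stride[1]; sw <- lp$stride[2]
  dh <- lp$dilation[1]; dw <- lp$dilation[2]
  oh <- conv_out_dim(h, kh, sh, dh); ow <- conv_out_dim(w, kw, sw, dw)
  f_n <- ncol(p$W)
  out <- array(0, c(oh, ow, f_n))
  for (f in seq_len(f_n)) {
    for (oc in seq_len(ow)) {
      for (or in seq_len(oh)) {
        acc <- p$b[f]
        for (ch in seq_len(cin)) {
          for (kc in seq_len(kw)) {
            for (kr in seq_len(kh)) {
              r <- (or - 1L) * sh + (kr - 1L) * dh + 1L
              cc <- (oc - 1L) * sw + (kc - 1L) * dw + 1L
              q <- (ch - 1L) * kh * kw + (kc - 1L) * kh + kr
              acc <- acc + x[r, cc, ch] * p$W[q, f]
              ct$mult <- ct$mult + 1; ct$add <- ct$add + 1
              ct$mac <- ct$mac + 1
            }
          }
        }
        out[or, oc, f] <- acc
      }
    }
  }
  out
}

oracle_instnorm <- function(x, p, ct) {
  d <- dim(x); m <- d[1] * d[2]
  out <- x
  for (ch in seq_len(d[3])) {
    acc <- 0
    for (v in x[, , ch]) { acc <- acc + v; ct$add <- ct$add + 1 }
    mu <- acc * (1 / m); ct$mult <- ct$mult + 1
    xc <- x[, , ch] - mu; ct$add <- ct$add + m
    acc <- 0
    for (v in xc) { acc <- acc + v * v; ct$mult <- ct$mult + 1
                    ct$add <- ct$add + 1 }
    v_ <- acc * (1 / m); ct$mult <- ct$mult + 1
    inv <- 1 / sqrt(v_ + EPS_NORM)          # rsqrt not counted
    xhat <- xc * inv; ct$mult <- ct$mult + m
    out[, , ch] <- xhat * p$gamma[ch] + p$beta[ch]
    ct$mult <- ct$mult + m; ct$add <- ct$add + m
  }
  out
}

oracle_rnn <- function(kind, x, p, ct) {
  if (kind == "bilstm") {
    fwd <- oracle_rnn("lstm", x, p$fwd, ct)
    bwd <- oracle_rnn("lstm", x[, rev(seq_len(ncol(x))), drop = FALSE],
                      p$bwd, ct)
    return(rbind(fwd, bwd[, rev(seq_len(ncol(x))), drop = FALSE]))
  }
  d <- nrow(x); t_len <- ncol(x)
  n_gates <- if (kind == "lstm") 4L else 3L
  h <- length(p$b) / n_gates
  dot <- function(block, t, hprev, with_bias = TRUE, x_part = TRUE,
                  h_part = TRUE) {
    vapply(seq_len(h), function(j) {
      col <- (block - 1L) * h + j
      acc <- if (with_bias) p$b[col] else 0
      if (x_part) for (k in seq_len(d)) {
        acc <- acc + x[k, t] * p$W[k, col]
        ct$mult <- ct$mult + 1; ct$add <- ct$add + 1; ct$mac <- ct$mac + 1
      }
      if (h_part) for (k in seq_len(h)) {
        acc <- acc + hprev[k] * p$U[k, col]
        ct$mult <- ct$mult + 1; ct$add <- ct$add + 1; ct$mac <- ct$mac + 1
      }
      acc
    }, 0)
  }
  out <- matrix(0, h, t_len)
  hprev <- rep(0, h)
  if (kind == "lstm") {
    cprev <- rep(0, h)
    for (t in seq_len(t_len)) {
      i <- sigmoid(dot(1L, t, hprev))
      f <- sigmoid(dot(2L, t, hprev))
      g <- tanh(dot(3L, t, hprev))
      o <- sigmoid(dot(4L, t, hprev))
      cprev <- f * cprev + i * g               # 2h mult, h add
      ct$mult <- ct$mult + 2 * h; ct$add <- ct$add + h
      hprev <- o * tanh(cprev)                 # h mult
      ct$mult <- ct$mult + h
      out[, t] <- hprev
    }
  } else {
    for (t in seq_len(t_len)) {
      r <- sigmoid(dot(1L, t, hprev))
      z <- sigmoid(dot(2L, t, hprev))
      xn <- dot(3L, t, hprev, with_bias = TRUE, h_part = FALSE)
      hun <- dot(3L, t, hprev, with_bias = FALSE, x_part = FALSE)
      nn <- tanh(xn + r * hun)                 # h mult, h add
      ct$mult <- ct$mult + h; ct$add <- ct$add + h
      hprev <- (1 - z) * nn + z * hprev        # 2h mult, 2h add
      ct$mult <- ct$mult + 2 * h; ct$add <- ct$add + 2 * h
      out[, t] <- hprev
    }
  }
  out
}

oracle_softmax <- function(x, ct) {
  o <- length(x)
  e <- exp(x - max(x))                         # exp/max-shift not counted
  acc <- 0
  for (v in e) { acc <- acc + v; ct$add <- ct$add + 1 }
  out <- e * (1 / acc); ct$mult <- ct$mult + o
  out
}
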