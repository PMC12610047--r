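# Layer-level forward and backward passes.
#
# Activations travel as dense arrays: sequence states are (n, d, T) arrays,
# image states (n, h, w, c) arrays, both column-major. Every backward
# function consumes the gradient of the loss w.r.t. its output and returns
# the gradient w.r.t. its input plus parameter gradients with the same
# structure as the parameters. All code is batch-vectorized; per-timestep
# recurrences are the only loops.

EPS_NORM <- 1e-5

# ---- dense ---------------------------------------------------------------

dense_forward <- function(x, p) {
  d <- dim(x)                                     # (n, din, T)
  xm <- matrix(aperm(x, c(1, 3, 2)), nrow = d[1] * d[3])
  y <- sweep(xm %*% p$W, 2L, p$b, `+`)
  out <- aperm(array(y, dim = c(d[1], d[3], ncol(p$W))), c(1, 3, 2))
  list(out = out, cache = list(xm = xm, dims = d))
}

dense_backward <- function(dy, p, cache) {
  d <- cache$dims
  dym <- matrix(aperm(dy, c(1, 3, 2)), nrow = d[1] * d[3])
  dx <- aperm(array(dym %*% t(p$W), dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  list(dx = dx, grads = list(W = crossprod(cache$xm, dym),
                             b = colSums(dym)))
}

# encoder_dense = dense + log-sigmoid transfer
encoder_forward <- function(x, p) {
  fw <- dense_forward(x, p)
  a <- sigmoid(fw$out)
  list(out = a, cache = list(dense = fw$cache, act = a))
}

encoder_backward <- function(dy, p, cache) {
  dpre <- dy * cache$act * (1 - cache$act)
  dense_backward(dpre, p, cache$dense)
}

# ---- LSTM / BiLSTM -------------------------------------------------------
# Gate order within the 4h blocks: input, forget, cell, output. One bias
# vector per gate set.

lstm_dir_forward <- function(x, p) {
  k <- lstm_cell_forward(x, p$W, p$U, p$b)
  k$x <- x
  list(h_all = k$H, cache = k)
}

lstm_dir_backward <- function(dh_all, p, cache) {
  g <- lstm_cell_backward(dh_all, cache$x, p$W, p$U, cache$I, cache$F,
                          cache$G, cache$O, cache$C, cache$TC, cache$H)
  list(dx = g$dx, grads = list(W = g$dW, U = g$dU, b = as.numeric(g$db)))
}

rev_time <- function(x) {
  t_len <- dim(x)[3]
  x[, , rev(seq_len(t_len)), drop = FALSE]
}

lstm_forward <- function(x, p, return_sequence) {
  fw <- lstm_dir_forward(x, p)
  t_len <- dim(x)[3]
  out <- if (return_sequence) fw$h_all
         else fw$h_all[, , t_len, drop = FALSE]
  list(out = out, cache = fw$cache)
}

lstm_backward <- function(dy, p, cache, return_sequence) {
  d <- dim(cache$x); h <- nrow(p$U)
  dh_all <- if (return_sequence) dy else {
    z <- array(0, c(d[1], h, d[3])); z[, , d[3]] <- dy[, , 1L]; z
  }
  lstm_dir_backward(dh_all, p, cache)
}

bilstm_forward <- function(x, p, return_sequence) {
  fw <- lstm_dir_forward(x, p$fwd)
  bw <- lstm_dir_forward(rev_time(x), p$bwd)
  n <- dim(x)[1]; t_len <- dim(x)[3]; h <- nrow(p$fwd$U)
  if (return_sequence) {
    out <- array(0, c(n, 2L * h, t_len))
    out[, seq_len(h), ] <- fw$h_all
    out[, h + seq_len(h), ] <- rev_time(bw$h_all)
  } else {
    # each direction's final state: forward at t = T, backward after the
    # full reverse pass (original t = 1)
    out <- array(0, c(n, 2L * h, 1L))
    out[, seq_len(h), 1L] <- fw$h_all[, , t_len]
    out[, h + seq_len(h), 1L] <- bw$h_all[, , t_len]
  }
  list(out = out, cache = list(fwd = fw$cache, bwd = bw$cache, h = h))
}

bilstm_backward <- function(dy, p, cache, return_sequence) {
  h <- cache$h
  if (return_sequence) {
    dfw <- dy[, seq_len(h), , drop = FALSE]
    dbw <- rev_time(dy[, h + seq_len(h), , drop = FALSE])
    gf <- lstm_dir_backward(dfw, p$fwd, cache$fwd)
    gb <- lstm_dir_backward(dbw, p$bwd, cache$bwd)
  } else {
    gf <- lstm_backward(dy[, seq_len(h), , drop = FALSE], p$fwd, cache$fwd,
                        FALSE)
    gb <- lstm_backward(dy[, h + seq_len(h), , drop = FALSE], p$bwd,
                        cache$bwd, FALSE)
  }
  list(dx = gf$dx + rev_time(gb$dx),
       grads = list(fwd = gf$grads, bwd = gb$grads))
}

# ---- GRU -----------------------------------------------------------------
# Block order within the 3h matrices: reset, update, candidate. Candidate
# uses the reset gate on the recurrent term: n = tanh(Wn x + r * (Un h) + bn).

gru_forward <- function(x, p, return_sequence) {
  k <- gru_cell_forward(x, p$W, p$U, p$b)
  k$x <- x
  t_len <- dim(x)[3]
  out <- if (return_sequence) k$H else k$H[, , t_len, drop = FALSE]
  list(out = out, cache = k)
}

gru_backward <- function(dy, p, cache, return_sequence) {
  d <- dim(cache$x); n <- d[1]; t_len <- d[3]; h <- nrow(p$U)
  dh_all <- if (return_sequence) dy else {
    z <- array(0, c(n, h, t_len)); z[, , t_len] <- dy[, , 1L]; z
  }
  g <- gru_cell_backward(dh_all, cache$x, p$W, p$U, cache$R, cache$Z,
                         cache$N, cache$HUn, cache$H)
  list(dx = g$dx, grads = list(W = g$dW, U = g$dU, b = as.numeric(g$db)))
}

# ---- conv2d --------------------------------------------------------------

conv_geometry <- function(in_shape, kernel, stride, dilation) {
  h <- in_shape[1]; w <- in_shape[2]; cin <- in_shape[3]
  kh <- kernel[1]; kw <- kernel[2]
  oh <- conv_out_dim(h, kh, stride[1], dilation[1])
  ow <- conv_out_dim(w, kw, stride[2], dilation[2])
  # patch index matrix: rows = output positions (oh*ow), cols = taps
  # (kh*kw*cin); entries are column indices into the (n, h*w*cin) matrix
  or_ <- rep(seq_len(oh), times = ow); oc_ <- rep(seq_len(ow), each = oh)
  kr <- rep(seq_len(kh), times = kw); kc <- rep(seq_len(kw), each = kh)
  r_idx <- outer((or_ - 1L) * stride[1] + 1L, (kr - 1L) * dilation[1], `+`)
  c_idx <- outer((oc_ - 1L) * stride[2] + 1L, (kc - 1L) * dilation[2], `+`)
  base <- r_idx + (c_idx - 1L) * h                      # (P, kh*kw)
  m <- matrix(0L, nrow = oh * ow, ncol = kh * kw * cin)
  for (ch in seq_len(cin)) {
    m[, (ch - 1L) * kh * kw + seq_len(kh * kw)] <- base + (ch - 1L) * h * w
  }
  list(oh = oh, ow = ow, cin = cin, h = h, w = w, m = m,
       q = kh * kw * cin, p = oh * ow)
}

# chunk size keeping the patch matrix under ~16M doubles
conv_chunks <- function(n, p, q) {
  per <- max(1L, as.integer(floor(16e6 / (p * q))))
  split(seq_len(n), ceiling(seq_len(n) / per))
}

conv_forward <- function(x, p, geom) {
  n <- dim(x)[1]
  xm <- matrix(x, nrow = n)                            # (n, h*w*cin)
  f <- ncol(p$W)
  out <- matrix(0, nrow = n * geom$p, ncol = f)
  for (idx in conv_chunks(n, geom$p, geom$q)) {
    pm <- matrix(array(xm[idx, as.vector(geom$m), drop = FALSE],
                       dim = c(length(idx), geom$p, geom$q)),
                 nrow = length(idx) * geom$p)
    y <- sweep(pm %*% p$W, 2L, p$b, `+`)
    rows <- as.vector(outer(idx, (seq_len(geom$p) - 1L) * n, `+`))
    out[rows, ] <- y
  }
  list(out = array(out, dim = c(n, geom$oh, geom$ow, f)),
       cache = list(xm = xm, geom = geom))
}

conv_backward <- function(dy, p, cache) {
  geom <- cache$geom
  n <- dim(dy)[1]; f <- ncol(p$W)
  dym <- matrix(dy, nrow = n * geom$p)                 # (n*P, F)
  dW <- matrix(0, nrow = geom$q, ncol = f)
  dxm <- matrix(0, nrow = n, ncol = geom$h * geom$w * geom$cin)
  for (idx in conv_chunks(n, geom$p, geom$q)) {
    rows <- as.vector(outer(idx, (seq_len(geom$p) - 1L) * n, `+`))
    pm <- matrix(array(cache$xm[idx, as.vector(geom$m), drop = FALSE],
                       dim = c(length(idx), geom$p, geom$q)),
                 nrow = length(idx) * geom$p)
    dyc <- dym[rows, , drop = FALSE]
    dW <- dW + crossprod(pm, dyc)
    dp <- array(dyc %*% t(p$W), dim = c(length(idx), geom$p, geom$q))
    for (q in seq_len(geom$q)) {
      cols <- geom$m[, q]
      dxm[idx, cols] <- dxm[idx, cols] + dp[, , q]
    }
  }
  list(dx = array(dxm, dim = c(n, geom$h, geom$w, geom$cin)),
       grads = list(W = dW, b = colSums(dym)))
}

# ---- instance normalization ---------------------------------------------
# Per-observation, per-channel normalization over the spatial positions,
# with learnable per-channel scale and shift.

instnorm_forward <- function(x, p) {
  d <- dim(x); n <- d[1]; m <- d[2] * d[3]; cc <- d[4]
  xm <- matrix(aperm(array(x, c(n, m, cc)), c(2, 1, 3)), nrow = m)  # (m, n*c)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + EPS_NORM)
  xhat <- sweep(xc, 2L, inv, `*`)
  gam <- rep(p$gamma, each = n); bet <- rep(p$beta, each = n)
  ym <- sweep(sweep(xhat, 2L, gam, `*`), 2L, bet, `+`)
  y <- array(aperm(array(ym, c(m, n, cc)), c(2, 1, 3)), dim = d)
  list(out = y, cache = list(xhat = xhat, inv = inv, dims = d))
}

instnorm_backward <- function(dy, p, cache) {
  d <- cache$dims; n <- d[1]; m <- d[2] * d[3]; cc <- d[4]
  dym <- matrix(aperm(array(dy, c(n, m, cc)), c(2, 1, 3)), nrow = m)
  xhat <- cache$xhat
  gam <- rep(p$gamma, each = n)
  dgamma_nc <- colSums(dym * xhat)
  dbeta_nc <- colSums(dym)
  dxhat <- sweep(dym, 2L, gam, `*`)
  mean_dxhat <- colMeans(dxhat)
  mean_dxx <- colMeans(dxhat * xhat)
  dxm <- sweep(sweep(sweep(dxhat, 2L, mean_dxhat), 1L, rep(1, m), `*`) -
                 sweep(xhat, 2L, mean_dxx, `*`),
               2L, cache$inv, `*`)
  dx <- array(aperm(array(dxm, c(m, n, cc)), c(2, 1, 3)), dim = d)
  list(dx = dx,
       grads = list(gamma = colSums(matrix(dgamma_nc, n, cc)),
                    beta = colSums(matrix(dbeta_nc, n, cc))))
}

# ---- shape plumbing and activations -------------------------------------

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

flatten_forward <- function(x, keep_time) {
  d <- dim(x)
  if (length(d) == 4L) {
    if (keep_time) {
      out <- array(aperm(x, c(1, 2, 4, 3)), dim = c(d[1], d[2] * d[4], d[3]))
    } else {
      out <- array(x, dim = c(d[1], d[2] * d[3] * d[4], 1L))
    }
  } else {
    out <- if (keep_time) x else array(x, dim = c(d[1], d[2] * d[3], 1L))
  }
  list(out = out, cache = d)
}

flatten_backward <- function(dy, keep_time, in_dims) {
  d <- in_dims
  if (length(d) == 4L) {
    if (keep_time) {
      aperm(array(dy, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
    } else {
      array(dy, dim = d)
    }
  } else {
    array(dy, dim = d)
  }
}

softmax_forward <- function(x) {
  d <- dim(x)
  z <- matrix(x, nrow = d[1])
  p <- softmax_rows(z)
  list(out = array(p, dim = d), cache = p)
}

softmax_backward <- function(dy, cache) {
  d <- dim(dy)
  dym <- matrix(dy, nrow = d[1])
  p <- cache
  dz <- p * (dym - rowSums(dym * p))
  array(dz, dim = d)
}
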