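# Network runtime: weight initialization, whole-network forward/backward,
# Adam training, prediction, and the per-timestep recurrence oracle.

glorot <- function(nr, nc, fan_in = nr, fan_out = nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# Glorot-uniform weights per gate block, zero biases, LSTM forget-gate bias 1.
init_rnn_dir <- function(d, h, n_gates, forget_bias = FALSE) {
  w <- do.call(cbind, replicate(n_gates, glorot(d, h, d, h), simplify = FALSE))
  u <- do.call(cbind, replicate(n_gates, glorot(h, h, h, h), simplify = FALSE))
  b <- rep(0, n_gates * h)
  if (forget_bias) b[h + seq_len(h)] <- 1     # forget gate block
  list(W = w, U = u, b = b)
}

#' Initialize a parameter store for an architecture
#'
#' Glorot-uniform weights (per gate block for recurrent layers), zero biases
#' except the LSTM forget-gate bias (1), unit scale / zero shift for instance
#' normalization. Deterministic given `seed`.
#'
#' @param spec An `arch_spec`.
#' @param seed Integer seed.
#' @return List of per-layer parameter lists (NULL for parameter-free
#'   layers), with attribute `shapes` (the [infer_shapes()] table).
#' @export
init_params <- function(spec, seed = 1L) {
  shapes <- infer_shapes(spec)
  withr::with_seed(seed, {
    params <- vector("list", length(spec$layers))
    st <- NULL
    for (i in seq_along(spec$layers)) {
      ly <- spec$layers[[i]]
      p <- ly$params
      din <- if (i > 1L) {
        prev <- shapes$shape[[i - 1L]]
        if (prev$type == "seq") prev$d else NA_integer_
      } else NA_integer_
      params[i] <- list(switch(ly$kind,
        dense = ,
        encoder_dense = list(W = glorot(din, p$out), b = rep(0, p$out)),
        bilstm = list(fwd = init_rnn_dir(din, p$h, 4L, forget_bias = TRUE),
                      bwd = init_rnn_dir(din, p$h, 4L, forget_bias = TRUE)),
        lstm = init_rnn_dir(din, p$h, 4L, forget_bias = TRUE),
        gru = init_rnn_dir(din, p$h, 3L),
        conv2d = {
          prev <- shapes$shape[[i - 1L]]
          q <- p$kernel[1] * p$kernel[2] * prev$c
          list(W = glorot(q, p$filters), b = rep(0, p$filters))
        },
        instance_norm = {
          prev <- shapes$shape[[i - 1L]]
          list(gamma = rep(1, prev$c), beta = rep(0, prev$c))
        },
        NULL))
    }
    attr(params, "shapes") <- shapes
    params
  })
}

#' Count parameters actually stored in a parameter list
#' @param params Output of [init_params()].
#' @return Integer total of all weight and bias elements.
#' @export
n_params <- function(params) {
  total <- 0L
  walk <- function(x) {
    if (is.numeric(x)) total <<- total + length(x)
    else if (is.list(x)) lapply(x, walk)
    invisible(NULL)
  }
  walk(params)
  total
}

#' Whole-network forward pass
#'
#' @param spec An `arch_spec`.
#' @param params Parameter store from [init_params()].
#' @param x Input array `(n, channels, win)`.
#' @return List with `out` (final activation, `(n, d, 1)` for classifiers),
#'   `probs` (n x d matrix after the softmax layer, if present), `logits`
#'   (pre-softmax matrix), and `caches` for the backward pass.
#' @export
forward_pass <- function(spec, params, x) {
  a <- x
  caches <- vector("list", length(spec$layers))
  logits <- NULL; probs <- NULL
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]; p <- params[[i]]
    r <- switch(ly$kind,
      sequence_input = list(out = a, cache = NULL),
      seq_fold = {
        d <- dim(a)
        list(out = array(a, dim = c(d, 1L)), cache = d)
      },
      seq_unfold = list(out = a, cache = NULL),
      conv2d = {
        d <- dim(a)
        geom <- conv_geometry(d[2:4], ly$params$kernel, ly$params$stride,
                              ly$params$dilation)
        conv_forward(a, p, geom)
      },
      instance_norm = instnorm_forward(a, p),
      relu = relu_forward(a),
      flatten = flatten_forward(a, isTRUE(ly$params$keep_time)),
      bilstm = bilstm_forward(a, p, isTRUE(ly$params$return_sequence)),
      lstm = lstm_forward(a, p, isTRUE(ly$params$return_sequence)),
      gru = gru_forward(a, p, isTRUE(ly$params$return_sequence)),
      dense = dense_forward(a, p),
      encoder_dense = encoder_forward(a, p),
      softmax = {
        logits <- matrix(a, nrow = dim(a)[1])
        sf <- softmax_forward(a)
        probs <- sf$cache
        sf
      },
      classification_output = list(out = a, cache = NULL),
      stop("unsupported layer kind: ", ly$kind, call. = FALSE))
    caches[[i]] <- r$cache
    a <- r$out
  }
  list(out = a, probs = probs, logits = logits, caches = caches)
}

#' Whole-network backward pass
#'
#' Backpropagates `dout` (gradient w.r.t. the activation entering layer
#' `from + 1`, or the network output) down to the input, collecting parameter
#' gradients. For cross-entropy training pass the gradient w.r.t. the
#' softmax *input* and set `from` to the layer before the softmax.
#'
#' @param spec,params,fw Architecture, parameters, and the matching
#'   [forward_pass()] result.
#' @param dout Gradient array shaped like layer `from`'s output.
#' @param from Index of the deepest layer to backpropagate through
#'   (default: last layer).
#' @return List with `grads` (same structure as `params`) and `dx`.
#' @export
backward_pass <- function(spec, params, fw, dout,
                          from = length(spec$layers)) {
  grads <- vector("list", length(spec$layers))
  dy <- dout
  for (i in seq(from, 1L)) {
    ly <- spec$layers[[i]]; p <- params[[i]]; cache <- fw$caches[[i]]
    r <- switch(ly$kind,
      sequence_input = list(dx = dy, grads = NULL),
      seq_fold = list(dx = array(dy, dim = cache), grads = NULL),
      seq_unfold = list(dx = dy, grads = NULL),
      conv2d = conv_backward(dy, p, cache),
      instance_norm = instnorm_backward(dy, p, cache),
      relu = list(dx = dy * cache, grads = NULL),
      flatten = list(dx = flatten_backward(dy, isTRUE(ly$params$keep_time),
                                           cache), grads = NULL),
      bilstm = bilstm_backward(dy, p, cache,
                               isTRUE(ly$params$return_sequence)),
      lstm = lstm_backward(dy, p, cache, isTRUE(ly$params$return_sequence)),
      gru = gru_backward(dy, p, cache, isTRUE(ly$params$return_sequence)),
      dense = dense_backward(dy, p, cache),
      encoder_dense = encoder_backward(dy, p, cache),
      softmax = list(dx = softmax_backward(dy, cache), grads = NULL),
      classification_output = list(dx = dy, grads = NULL))
    grads[i] <- list(r$grads)
    dy <- r$dx
  }
  list(grads = grads, dx = dy)
}

# ---- parameter-structure arithmetic -------------------------------------

map_leaves <- function(f, ...) {
  args <- list(...)
  x <- args[[1L]]
  if (is.numeric(x)) return(do.call(f, args))
  if (is.list(x)) {
    out <- x
    for (k in seq_along(x)) {
      out[k] <- list(do.call(map_leaves, c(list(f), lapply(args, `[[`, k))))
    }
    return(out)
  }
  x
}

zero_like <- function(params) map_leaves(function(x) x * 0, params)

# sum of squared weights (biases and normalization parameters excluded)
weight_sq_sum <- function(params) {
  total <- 0
  walk <- function(x, nm) {
    if (is.numeric(x)) {
      if (nm %in% c("W", "U")) total <<- total + sum(x * x)
    } else if (is.list(x)) {
      for (k in seq_along(x)) walk(x[[k]], names(x)[k] %||% "")
    }
  }
  walk(params, "")
  total
}

add_l2_grads <- function(grads, params, l2) {
  walk <- function(g, p, nm) {
    if (is.numeric(p)) {
      if (nm %in% c("W", "U")) g + l2 * p else g
    } else if (is.list(p)) {
      for (k in seq_along(p)) {
        g[k] <- list(walk(g[[k]], p[[k]], names(p)[k] %||% ""))
      }
      g
    } else g
  }
  walk(grads, params, "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- training ------------------------------------------------------------

#' Training configuration
#'
#' Adam with the piecewise learning-rate schedule
#' `lr_t = initial_lr * lr_drop_factor^floor(epoch / lr_drop_period)`,
#' cross-entropy loss, and L2 weight decay on all weight matrices (biases
#' excluded).
#'
#' @param optimizer `"adam"`.
#' @param max_epochs Number of epochs (>= 1).
#' @param batch_size Minibatch size (default 128).
#' @param initial_lr Initial learning rate (default 1e-3).
#' @param lr_drop_factor Multiplicative drop (default 0.1).
#' @param lr_drop_period Epochs between drops (default 10). The schedule is
#'   applied as printed; `lr_floor` optionally caps the decay (0 disables the
#'   cap), since the literal schedule reaches ~1e-253 by epoch 2500.
#' @param l2 L2 regularization coefficient (default 1e-4).
#' @param lr_floor Minimum learning rate (default 0 = no floor).
#' @param seed Integer seed for initialization and batch shuffling.
#' @return A `train_config` object.
#' @export
train_config <- function(optimizer = "adam", max_epochs = 30L,
                         batch_size = 128L, initial_lr = 1e-3,
                         lr_drop_factor = 0.1, lr_drop_period = 10L,
                         l2 = 1e-4, lr_floor = 0, seed = 1L) {
  if (!optimizer %in% c("adam")) {
    stop("unsupported optimizer: ", optimizer, call. = FALSE)
  }
  check_count(max_epochs, "max_epochs")
  check_count(batch_size, "batch_size")
  check_positive(initial_lr, "initial_lr")
  if (lr_drop_factor <= 0 || lr_drop_factor > 1) {
    stop("`lr_drop_factor` must be in (0, 1]", call. = FALSE)
  }
  check_count(lr_drop_period, "lr_drop_period")
  check_non_negative(l2, "l2")
  structure(list(optimizer = optimizer, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, lr_drop_factor = lr_drop_factor,
                 lr_drop_period = as.integer(lr_drop_period), l2 = l2,
                 lr_floor = lr_floor, seed = as.integer(seed)),
            class = "train_config")
}

#' Train a classifier network on a segment set
#'
#' Minimizes cross-entropy plus L2 weight decay with Adam under the
#' piecewise learning-rate schedule. Deterministic given the configuration
#' seed. Layers listed in `frozen_layers` keep their (possibly pretrained)
#' parameters fixed.
#'
#' @param segments Training [segment_set()] (>= 2 classes present).
#' @param spec An `arch_spec` classifier.
#' @param config A [train_config()].
#' @param init Optional pre-initialized parameter store (e.g. containing a
#'   pretrained encoder).
#' @param frozen_layers Integer indices of layers excluded from updates.
#' @return A `har_model`: list with `spec`, `params`, `history` (tibble of
#'   per-epoch loss and learning rate), `classes`, `config`.
#' @export
train_network <- function(segments, spec, config = train_config(),
                          init = NULL, frozen_layers = integer(0)) {
  stopifnot(inherits(spec, "arch_spec"))
  n <- n_segments(segments)
  if (n < 1L) stop("empty training set", call. = FALSE)
  if (length(unique(segments$y)) < 2L) {
    stop("degenerate labels: training set contains a single class",
         call. = FALSE)
  }
  classes <- activity_classes()
  y_idx <- as.integer(segments$y)
  n_cls <- spec$n_classes
  softmax_at <- which(vapply(spec$layers, `[[`, "", "kind") == "softmax")
  if (length(softmax_at) != 1L) {
    stop("classifier spec must contain exactly one softmax layer",
         call. = FALSE)
  }
  params <- init %||% init_params(spec, seed = config$seed)
  m_state <- zero_like(params); v_state <- zero_like(params)
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  step <- 0L
  history <- matrix(0, nrow = config$max_epochs, ncol = 2L)

  withr::with_seed(derive_seed(config$seed, 555L), {
    for (epoch in seq_len(config$max_epochs)) {
      lr <- config$initial_lr *
        config$lr_drop_factor^((epoch - 1L) %/% config$lr_drop_period)
      if (config$lr_floor > 0) lr <- max(lr, config$lr_floor)
      perm <- sample(n)
      ep_loss <- 0; ep_n <- 0L
      for (b0 in seq(1L, n, by = config$batch_size)) {
        idx <- perm[b0:min(b0 + config$batch_size - 1L, n)]
        nb <- length(idx)
        xb <- segments$x[idx, , , drop = FALSE]
        fw <- forward_pass(spec, params, xb)
        p_true <- fw$probs[cbind(seq_len(nb), y_idx[idx])]
        loss <- -mean(log(pmax(p_true, 1e-12))) +
          0.5 * config$l2 * weight_sq_sum(params)
        if (!is.finite(loss)) {
          stop("divergence: non-finite loss at epoch ", epoch, call. = FALSE)
        }
        ep_loss <- ep_loss + loss * nb; ep_n <- ep_n + nb
        y_onehot <- matrix(0, nb, n_cls)
        y_onehot[cbind(seq_len(nb), y_idx[idx])] <- 1
        dlogits <- (fw$probs - y_onehot) / nb
        bw <- backward_pass(spec, params, fw,
                            array(dlogits, dim = c(nb, n_cls, 1L)),
                            from = softmax_at - 1L)
        grads <- add_l2_grads(bw$grads, params, config$l2)
        for (li in frozen_layers) grads[[li]] <- zero_like(params[[li]])
        step <- step + 1L
        bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
        m_state <- map_leaves(function(m, g) beta1 * m + (1 - beta1) * g,
                              m_state, grads)
        v_state <- map_leaves(function(v, g) beta2 * v + (1 - beta2) * g * g,
                              v_state, grads)
        params <- map_leaves(function(p, m, v)
          p - lr * (m / bc1) / (sqrt(v / bc2) + adam_eps),
          params, m_state, v_state)
      }
      history[epoch, ] <- c(ep_loss / ep_n, lr)
    }
  })
  structure(list(spec = spec, params = params,
                 history = tibble::tibble(epoch = seq_len(config$max_epochs),
                                          loss = history[, 1],
                                          lr = history[, 2]),
                 classes = classes, config = config,
                 train_seed = config$seed),
            class = "har_model")
}

#' @export
print.har_model <- function(x, ...) {
  cat(sprintf("<har_model> %s: %d parameters, %d epochs, final loss %.4f\n",
              x$spec$name, n_params(x$params), nrow(x$history),
              x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' Predict class probabilities and labels for segments
#'
#' @param object A `har_model`.
#' @param segments A [segment_set()] (or bare `(n, channels, win)` array)
#'   whose window shape matches the model input.
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return Tibble with `.pred` (factor; argmax with lowest-index tie-break)
#'   and one `.prob_<class>` column per class; rows sum to 1.
#' @export
predict.har_model <- function(object, segments, batch_size = 128L, ...) {
  x <- if (inherits(segments, "segment_set")) segments$x else segments
  d <- dim(x)
  ishape <- object$spec$input_shape
  if (length(d) != 3L || d[2] != ishape[1] || d[3] != ishape[2]) {
    stop("input shape mismatch: expected (n, ", ishape[1], ", ", ishape[2],
         ")", call. = FALSE)
  }
  n <- d[1]
  probs <- matrix(0, n, object$spec$n_classes)
  for (b0 in seq(1L, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, n)
    fw <- forward_pass(object$spec, object$params,
                       x[idx, , , drop = FALSE])
    probs[idx, ] <- fw$probs
  }
  labels <- factor(object$classes[max.col(probs, ties.method = "first")],
                   levels = object$classes)
  out <- tibble::tibble(.pred = labels)
  for (k in seq_along(object$classes)) {
    out[[paste0(".prob_", object$classes[k])]] <- probs[, k]
  }
  out
}

# ---- reference recurrence oracle ----------------------------------------

#' Per-timestep reference recurrence (test oracle)
#'
#' Straight-line scalar implementation of the standard LSTM/GRU/BiLSTM
#' update equations, one unit and one timestep at a time, with no matrix
#' algebra. Used to pin the batched production layers: both must agree to
#' ~1e-5 elementwise for shared random weights. Intended for tiny sizes
#' (h <= 8, T <= 16).
#'
#' @param kind `"lstm"`, `"gru"` or `"bilstm"`.
#' @param weights For lstm/gru a list `W`, `U`, `b` (gate blocks stacked
#'   column-wise in the documented order); for bilstm a list `fwd`, `bwd` of
#'   such lists.
#' @param x Input matrix `d x T` (one sequence).
#' @return Hidden-state matrix `h x T` (`2h x T` for bilstm, forward
#'   direction stacked on backward, both aligned to the original time axis).
#' @export
rnn_forward_oracle <- function(kind, weights, x) {
  kind <- match.arg(kind, c("lstm", "gru", "bilstm"))
  if (kind == "bilstm") {
    fwd <- rnn_forward_oracle("lstm", weights$fwd, x)
    bwd <- rnn_forward_oracle("lstm", weights$bwd, x[, rev(seq_len(ncol(x))),
                                                     drop = FALSE])
    return(rbind(fwd, bwd[, rev(seq_len(ncol(x))), drop = FALSE]))
  }
  d <- nrow(x); t_len <- ncol(x)
  n_gates <- if (kind == "lstm") 4L else 3L
  h <- length(weights$b) / n_gates
  gate_pre <- function(block, t, hprev) {
    # scalar dot products, unit by unit
    vapply(seq_len(h), function(j) {
      col <- (block - 1L) * h + j
      acc <- weights$b[col]
      for (k in seq_len(d)) acc <- acc + x[k, t] * weights$W[k, col]
      for (k in seq_len(h)) acc <- acc + hprev[k] * weights$U[k, col]
      acc
    }, 0)
  }
  out <- matrix(0, h, t_len)
  hprev <- rep(0, h)
  if (kind == "lstm") {
    cprev <- rep(0, h)
    for (t in seq_len(t_len)) {
      i <- sigmoid(gate_pre(1L, t, hprev))
      f <- sigmoid(gate_pre(2L, t, hprev))
      g <- tanh(gate_pre(3L, t, hprev))
      o <- sigmoid(gate_pre(4L, t, hprev))
      cprev <- f * cprev + i * g
      hprev <- o * tanh(cprev)
      out[, t] <- hprev
    }
  } else {
    for (t in seq_len(t_len)) {
      r <- sigmoid(gate_pre(1L, t, hprev))
      z <- sigmoid(gate_pre(2L, t, hprev))
      # candidate: reset gate applied to the recurrent product only
      hun <- vapply(seq_len(h), function(j) {
        col <- 2L * h + j
        acc <- 0
        for (k in seq_len(h)) acc <- acc + hprev[k] * weights$U[k, col]
        acc
      }, 0)
      xn <- vapply(seq_len(h), function(j) {
        col <- 2L * h + j
        acc <- weights$b[col]
        for (k in seq_len(d)) acc <- acc + x[k, t] * weights$W[k, col]
        acc
      }, 0)
      nn <- tanh(xn + r * hun)
      hprev <- (1 - z) * nn + z * hprev
      out[, t] <- hprev
    }
  }
  out
}
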