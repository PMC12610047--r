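# Sparse denoising autoencoder: loss, conjugate-gradient pretraining,
# and the two-phase classifier training (pretrain encoder, discard decoder,
# fit softmax head).

kl_bernoulli <- function(rho, rho_hat) {
  eps <- 1e-12
  clamped <- pmin(pmax(rho_hat, eps), 1 - eps)
  if (any(rho_hat <= 0 | rho_hat >= 1)) {
    warning("mean activations clamped to [1e-12, 1 - 1e-12]")
  }
  sum(rho * log(rho / clamped) + (1 - rho) * log((1 - rho) / (1 - clamped)))
}

#' Sparse MSE loss of the autoencoder
#'
#' `loss = mean((x - xhat)^2) + lambda * sum(W^2) + beta * sum_j KL(rho ||
#' rho_hat_j)` with the Bernoulli Kullback-Leibler divergence
#' `KL(rho || r) = rho log(rho/r) + (1 - rho) log((1 - rho)/(1 - r))`.
#' Mean activations at 0 or 1 are clamped to `[1e-12, 1 - 1e-12]` with a
#' warning.
#'
#' @param x Input batch (n x d matrix).
#' @param xhat Reconstruction (same shape).
#' @param weights List of weight matrices entering the L2 term (encoder and
#'   decoder).
#' @param rho_hat Per-hidden-unit mean activation vector (log-sigmoid
#'   outputs, in (0, 1)).
#' @param cfg An [spdae_config()] supplying `sparsity_proportion` (rho),
#'   `sparsity_regularization` (beta) and `l2` (lambda).
#' @return Non-negative scalar loss.
#' @export
#' @examples
#' cfg <- spdae_config(hidden_units = 2)
#' x <- matrix(rnorm(10), 5)
#' sparse_mse_loss(x, x, list(), rep(0.05, 2), cfg)  # 0: all terms vanish
sparse_mse_loss <- function(x, xhat, weights, rho_hat, cfg) {
  stopifnot(all(dim(x) == dim(xhat)))
  mse <- mean((x - xhat)^2)
  l2 <- cfg$l2 * sum(vapply(weights, function(w) sum(w * w), 0))
  kl <- cfg$sparsity_regularization *
    kl_bernoulli(cfg$sparsity_proportion, rho_hat)
  mse + l2 + kl
}

# Analytic loss + gradient of the sparse denoising autoencoder, on flattened
# parameter vector theta = [We, be, Wd, bd].
spdae_objective <- function(x_clean, x_corrupt, n_in, h, cfg) {
  n <- nrow(x_clean)
  iWe <- seq_len(n_in * h)
  ibe <- n_in * h + seq_len(h)
  iWd <- n_in * h + h + seq_len(h * n_in)
  ibd <- n_in * h + h + h * n_in + seq_len(n_in)
  unpack <- function(theta) {
    list(We = matrix(theta[iWe], n_in, h), be = theta[ibe],
         Wd = matrix(theta[iWd], h, n_in), bd = theta[ibd])
  }
  rho <- cfg$sparsity_proportion; beta <- cfg$sparsity_regularization
  lam <- cfg$l2
  fn <- function(theta) {
    p <- unpack(theta)
    hid <- sigmoid(sweep(x_corrupt %*% p$We, 2L, p$be, `+`))
    rho_hat <- colMeans(hid)
    xhat <- sweep(hid %*% p$Wd, 2L, p$bd, `+`)
    sparse_mse_loss(x_clean, xhat, list(p$We, p$Wd), rho_hat, cfg)
  }
  gr <- function(theta) {
    p <- unpack(theta)
    hid <- sigmoid(sweep(x_corrupt %*% p$We, 2L, p$be, `+`))
    rho_hat <- pmin(pmax(colMeans(hid), 1e-12), 1 - 1e-12)
    xhat <- sweep(hid %*% p$Wd, 2L, p$bd, `+`)
    dxhat <- 2 * (xhat - x_clean) / (n * n_in)
    dWd <- crossprod(hid, dxhat) + 2 * lam * p$Wd
    dbd <- colSums(dxhat)
    dhid <- dxhat %*% t(p$Wd)
    dkl <- beta * (-rho / rho_hat + (1 - rho) / (1 - rho_hat)) / n
    dhid <- sweep(dhid, 2L, dkl, `+`)
    dpre <- dhid * hid * (1 - hid)
    dWe <- crossprod(x_corrupt, dpre) + 2 * lam * p$We
    dbe <- colSums(dpre)
    c(as.vector(dWe), dbe, as.vector(dWd), dbd)
  }
  list(fn = fn, gr = gr, unpack = unpack)
}

# Unsupervised pretraining of the encoder on a design matrix (rows =
# examples). Conjugate gradient (full batch, analytic gradient) by default;
# Adam full-batch as fallback.
pretrain_encoder <- function(x, cfg, optimizer = c("cg", "adam")) {
  optimizer <- match.arg(optimizer)
  n_in <- ncol(x); h <- cfg$hidden_units
  withr::with_seed(cfg$seed, {
    x_corrupt <- if (cfg$corruption_sd > 0) {
      x + matrix(stats::rnorm(length(x), sd = cfg$corruption_sd), nrow(x))
    } else x
    theta0 <- c(as.vector(glorot(n_in, h)), rep(0, h),
                as.vector(glorot(h, n_in)), rep(0, n_in))
    obj <- spdae_objective(x, x_corrupt, n_in, h, cfg)
    if (optimizer == "cg") {
      fit <- stats::optim(theta0, obj$fn, obj$gr, method = "CG",
                          control = list(maxit = cfg$max_epochs))
      theta <- fit$par
      history <- c(obj$fn(theta0), fit$value)
    } else {
      theta <- theta0
      m <- theta * 0; v <- theta * 0
      history <- numeric(cfg$max_epochs)
      for (it in seq_len(cfg$max_epochs)) {
        g <- obj$gr(theta)
        m <- 0.9 * m + 0.1 * g
        v <- 0.999 * v + 0.001 * g * g
        theta <- theta - 1e-3 * (m / (1 - 0.9^it)) /
          (sqrt(v / (1 - 0.999^it)) + 1e-8)
        history[it] <- obj$fn(theta)
      }
    }
    c(obj$unpack(theta), list(history = history))
  })
}

#' Train a sparse denoising autoencoder classifier
#'
#' Phase one trains the autoencoder to reconstruct the flattened windows
#' from Gaussian-corrupted copies under the sparse MSE loss (conjugate
#' gradient by default). Phase two discards the decoder and fits the softmax
#' head on the frozen encoder features with Adam.
#'
#' @param segments Training [segment_set()].
#' @param arch An `spdae_arch` from [build_spdae()].
#' @param head_config [train_config()] for the supervised phase.
#' @param optimizer Pretraining optimizer, `"cg"` (default) or `"adam"`.
#' @return A `har_model` for the classifier spec, with the pretraining loss
#'   trace in `pretrain_history` and the decoder in `decoder`.
#' @export
train_spdae <- function(segments, arch = build_spdae(),
                        head_config = train_config(max_epochs = 30L),
                        optimizer = c("cg", "adam")) {
  stopifnot(inherits(arch, "spdae_arch"))
  x <- flatten_segments(segments)
  pre <- pretrain_encoder(x, arch$config, optimizer)
  spec <- arch$classifier
  enc_at <- which(vapply(spec$layers, `[[`, "", "kind") == "encoder_dense")
  params <- init_params(spec, seed = head_config$seed)
  params[[enc_at]] <- list(W = pre$We, b = pre$be)
  model <- train_network(segments, spec, head_config, init = params,
                         frozen_layers = enc_at)
  model$pretrain_history <- pre$history
  model$decoder <- list(W = pre$Wd, b = pre$bd)
  model
}

#' Train a recurrent Sp-DAE classifier
#'
#' Pretrains the encoder unsupervised (on flattened windows for the
#' `"window"` wiring, on per-sample channel vectors for `"timestep"`), then
#' trains the BiLSTM and softmax head on the frozen encoder features.
#'
#' @param segments Training [segment_set()].
#' @param spec An `arch_spec` from [build_recurrent_spdae()].
#' @param spdae_cfg [spdae_config()] for the pretraining phase (its
#'   `hidden_units` must match the spec's encoder width).
#' @param head_config [train_config()] for the supervised phase.
#' @param optimizer Pretraining optimizer.
#' @param max_pretrain_rows Cap on pretraining examples (timestep wiring
#'   yields one example per 240 Hz sample; a deterministic subsample keeps
#'   pretraining tractable).
#' @return A `har_model` with `pretrain_history`.
#' @export
train_recurrent_spdae <- function(segments, spec,
                                  spdae_cfg = spdae_config(),
                                  head_config = train_config(max_epochs = 30L),
                                  optimizer = c("cg", "adam"),
                                  max_pretrain_rows = 4000L) {
  stopifnot(inherits(spec, "arch_spec"))
  enc_at <- which(vapply(spec$layers, `[[`, "", "kind") == "encoder_dense")
  if (length(enc_at) != 1L) {
    stop("spec has no encoder_dense layer", call. = FALSE)
  }
  shapes <- infer_shapes(spec)
  enc_in <- shapes$shape[[enc_at - 1L]]$d
  if (spec$layers[[enc_at]]$params$out != spdae_cfg$hidden_units) {
    stop("encoder width of `spec` and `spdae_cfg$hidden_units` disagree",
         call. = FALSE)
  }
  x <- if (enc_in == prod(spec$input_shape)) {
    flatten_segments(segments)
  } else {
    # timestep wiring: one pretraining example per 240 Hz sample
    d <- dim(segments$x)
    m <- matrix(aperm(segments$x, c(1, 3, 2)), ncol = d[2])
    if (nrow(m) > max_pretrain_rows) {
      keep <- withr::with_seed(spdae_cfg$seed,
                               sort(sample(nrow(m), max_pretrain_rows)))
      m <- m[keep, , drop = FALSE]
    }
    m
  }
  pre <- pretrain_encoder(x, spdae_cfg, optimizer)
  params <- init_params(spec, seed = head_config$seed)
  params[[enc_at]] <- list(W = pre$We, b = pre$be)
  model <- train_network(segments, spec, head_config, init = params,
                         frozen_layers = enc_at)
  model$pretrain_history <- pre$history
  model
}
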