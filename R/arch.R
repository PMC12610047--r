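#' Declarative layer and architecture specifications
#'
#' An architecture spec is an ordered list of layer specs plus the input
#' shape; it is the single source of truth shared by the runtime models
#' (weight initialization, forward/backward passes) and the analytic
#' complexity profiler, guaranteeing that both see identical shapes.
#'
#' @param kind Layer kind: one of `"sequence_input"`, `"bilstm"`, `"lstm"`,
#'   `"gru"`, `"dense"`, `"softmax"`, `"conv2d"`, `"instance_norm"`,
#'   `"relu"`, `"seq_fold"`, `"seq_unfold"`, `"flatten"`, `"encoder_dense"`,
#'   `"classification_output"`.
#' @param ... Layer hyperparameters (`h`, `out`, `filters`, `kernel`,
#'   `stride`, `dilation`, `return_sequence`, `keep_time`, ...).
#' @return A `layer_spec` list.
#' @export
layer <- function(kind, ...) {
  kinds <- c("sequence_input", "bilstm", "lstm", "gru", "dense", "softmax",
             "conv2d", "instance_norm", "relu", "seq_fold", "seq_unfold",
             "flatten", "encoder_dense", "classification_output")
  if (!kind %in% kinds) stop("unsupported layer kind: ", kind, call. = FALSE)
  structure(list(kind = kind, params = list(...)), class = "layer_spec")
}

new_arch_spec <- function(name, layers, input_shape, n_classes = 7L) {
  spec <- structure(list(name = name, layers = layers,
                         input_shape = as.integer(input_shape),
                         n_classes = as.integer(n_classes)),
                    class = "arch_spec")
  infer_shapes(spec)  # fail fast on inconsistent chains
  spec
}

#' @export
print.arch_spec <- function(x, ...) {
  cat(sprintf("<arch_spec> %s: %d layers, input %s\n", x$name,
              length(x$layers), paste(x$input_shape, collapse = " x ")))
  print(infer_shapes(x))
  invisible(x)
}

# Internal shape-state helpers --------------------------------------------

shape_seq <- function(d, t) list(type = "seq", d = as.integer(d), t = as.integer(t))
shape_img <- function(h, w, c) list(type = "img", h = as.integer(h),
                                    w = as.integer(w), c = as.integer(c))

conv_out_dim <- function(n, k, s, d) {
  dk <- (k - 1L) * d + 1L
  as.integer(floor((n - dk) / s) + 1L)
}

#' Infer per-layer output shapes of an architecture
#'
#' Walks the layer chain applying the standard valid-convolution formula
#' `out = floor((in - dilated_kernel)/stride) + 1` with
#' `dilated_kernel = (k - 1) * dilation + 1`, recurrent and dense dimension
#' rules, and sequence fold/unfold/flatten reshapes. Errors (naming the
#' offending layer) if any intermediate dimension is non-positive.
#'
#' @param spec An `arch_spec`.
#' @return Tibble with one row per layer: `layer`, `kind`, `output` (printed
#'   shape) and a `shape` list-column of shape states.
#' @export
infer_shapes <- function(spec) {
  st <- shape_seq(spec$input_shape[1], spec$input_shape[2])
  rows <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    p <- ly$params
    st <- switch(ly$kind,
      sequence_input = shape_seq(spec$input_shape[1], spec$input_shape[2]),
      seq_fold = {
        stopifnot(st$type == "seq")
        shape_img(st$d, st$t, 1L)
      },
      seq_unfold = st,
      conv2d = {
        if (st$type != "img") stop("layer ", i, " (conv2d): needs image input",
                                   call. = FALSE)
        oh <- conv_out_dim(st$h, p$kernel[1], p$stride[1], p$dilation[1])
        ow <- conv_out_dim(st$w, p$kernel[2], p$stride[2], p$dilation[2])
        if (oh < 1 || ow < 1) {
          stop("layer ", i, " (conv2d): non-positive output shape ", oh, " x ",
               ow, call. = FALSE)
        }
        shape_img(oh, ow, p$filters)
      },
      instance_norm = st,
      relu = st,
      flatten = {
        keep <- isTRUE(p$keep_time)
        if (st$type == "img") {
          if (keep) shape_seq(st$h * st$c, st$w)
          else shape_seq(st$h * st$w * st$c, 1L)
        } else {
          if (keep) st else shape_seq(st$d * st$t, 1L)
        }
      },
      bilstm = ,
      lstm = ,
      gru = {
        if (st$type != "seq") stop("layer ", i, " (", ly$kind,
                                   "): needs sequence input", call. = FALSE)
        mult <- if (ly$kind == "bilstm") 2L else 1L
        shape_seq(p$h * mult, if (isTRUE(p$return_sequence)) st$t else 1L)
      },
      dense = ,
      encoder_dense = {
        if (st$type != "seq") stop("layer ", i, " (", ly$kind,
                                   "): needs sequence input", call. = FALSE)
        shape_seq(p$out, st$t)
      },
      softmax = st,
      classification_output = st,
      stop("unsupported layer kind: ", ly$kind, call. = FALSE)
    )
    rows[[i]] <- tibble::tibble(
      layer = i, kind = ly$kind,
      output = if (st$type == "seq") sprintf("%d x %d (seq)", st$d, st$t)
               else sprintf("%d x %d x %d (img)", st$h, st$w, st$c),
      shape = list(st))
  }
  dplyr::bind_rows(rows)
}

# Architecture builders ----------------------------------------------------

#' BiLSTM sequence classifier
#'
#' Five layers: sequence input of 10 channels, one bidirectional LSTM with
#' `hidden_units` units per direction (final state of each direction is the
#' window representation), a fully connected layer to `n_classes`, softmax,
#' and the cross-entropy classification output.
#'
#' @param hidden_units Hidden units per direction (>= 1).
#' @param n_in Input channels (default 10).
#' @param n_classes Number of classes (default 7).
#' @param win Window length in samples (default 240).
#' @return An `arch_spec`.
#' @export
#' @examples
#' count_learnables(build_bilstm(300))  # 750607
build_bilstm <- function(hidden_units, n_in = 10L, n_classes = 7L,
                         win = 240L) {
  check_count(hidden_units, "hidden_units")
  new_arch_spec(
    name = sprintf("bilstm_h%d", hidden_units),
    layers = list(
      layer("sequence_input"),
      layer("bilstm", h = as.integer(hidden_units), return_sequence = FALSE),
      layer("dense", out = as.integer(n_classes)),
      layer("softmax"),
      layer("classification_output")),
    input_shape = c(n_in, win), n_classes = n_classes)
}

#' Sparse denoising autoencoder (Sp-DAE) configuration
#'
#' @param hidden_units Encoder width.
#' @param max_epochs Pretraining epochs / CG iterations.
#' @param sparsity_regularization Weight `beta` of the KL sparsity penalty.
#' @param sparsity_proportion Target mean activation `rho` in (0, 1).
#' @param l2 Weight-decay coefficient `lambda`.
#' @param corruption_sd Standard deviation of the Gaussian input corruption
#'   applied during denoising pretraining.
#' @param seed Integer seed.
#' @return An `spdae_config` object.
#' @export
spdae_config <- function(hidden_units = 100L, max_epochs = 100L,
                         sparsity_regularization = 1,
                         sparsity_proportion = 0.05, l2 = 1e-4,
                         corruption_sd = 0.05, seed = 1L) {
  check_count(hidden_units, "hidden_units")
  check_count(max_epochs, "max_epochs")
  if (sparsity_proportion <= 0 || sparsity_proportion >= 1) {
    stop("`sparsity_proportion` must be in (0, 1)", call. = FALSE)
  }
  check_non_negative(sparsity_regularization, "sparsity_regularization")
  check_non_negative(l2, "l2")
  check_non_negative(corruption_sd, "corruption_sd")
  structure(list(hidden_units = as.integer(hidden_units),
                 max_epochs = as.integer(max_epochs),
                 sparsity_regularization = sparsity_regularization,
                 sparsity_proportion = sparsity_proportion, l2 = l2,
                 transfer = "log-sigmoid", corruption_sd = corruption_sd,
                 seed = as.integer(seed)),
            class = "spdae_config")
}

#' Sparse denoising autoencoder architecture pair
#'
#' Returns the unsupervised autoencoder spec (log-sigmoid encoder
#' `n_in -> h`, linear decoder `h -> n_in`) and the supervised classifier
#' spec (same encoder, decoder discarded, softmax head) that share encoder
#' weights. The input is the flattened window (10 x 240 = 2400 by default).
#'
#' @param cfg An [spdae_config()].
#' @param n_in Flattened input size.
#' @param n_classes Number of classes.
#' @param input_shape Window shape the flattening starts from.
#' @return An `spdae_arch` with fields `autoencoder`, `classifier`, `config`.
#' @export
build_spdae <- function(cfg = spdae_config(), n_in = 2400L, n_classes = 7L,
                        input_shape = c(10L, 240L)) {
  stopifnot(inherits(cfg, "spdae_config"))
  if (prod(input_shape) != n_in) {
    stop("`n_in` must equal prod(input_shape)", call. = FALSE)
  }
  h <- cfg$hidden_units
  ae <- new_arch_spec(
    name = sprintf("spdae_ae_h%d", h),
    layers = list(
      layer("sequence_input"),
      layer("flatten", keep_time = FALSE),
      layer("encoder_dense", out = h),
      layer("dense", out = as.integer(n_in))),
    input_shape = input_shape, n_classes = n_classes)
  clf <- new_arch_spec(
    name = sprintf("spdae_h%d", h),
    layers = list(
      layer("sequence_input"),
      layer("flatten", keep_time = FALSE),
      layer("encoder_dense", out = h),
      layer("dense", out = as.integer(n_classes)),
      layer("softmax"),
      layer("classification_output")),
    input_shape = input_shape, n_classes = n_classes)
  structure(list(autoencoder = ae, classifier = clf, config = cfg),
            class = "spdae_arch")
}

#' Recurrent Sp-DAE: BiLSTM stacked on the autoencoder's encoder
#'
#' The encoder compresses the input before the BiLSTM models temporal
#' structure. Two wirings are provided: `features = "window"` (default)
#' applies the encoder to the flattened window, handing the BiLSTM a
#' length-one feature sequence; `features = "timestep"` applies a 10-input
#' encoder to every 240 Hz sample, handing the BiLSTM a 240-step encoded
#' sequence.
#'
#' @param encoder_units Encoder width.
#' @param bilstm_units BiLSTM hidden units per direction.
#' @param features `"window"` or `"timestep"` (see Details).
#' @param n_classes Number of classes.
#' @param input_shape Window shape.
#' @return An `arch_spec`.
#' @export
build_recurrent_spdae <- function(encoder_units, bilstm_units,
                                  features = c("window", "timestep"),
                                  n_classes = 7L, input_shape = c(10L, 240L)) {
  check_count(encoder_units, "encoder_units")
  check_count(bilstm_units, "bilstm_units")
  features <- match.arg(features)
  pre <- if (features == "window") {
    list(layer("sequence_input"), layer("flatten", keep_time = FALSE),
         layer("encoder_dense", out = as.integer(encoder_units)))
  } else {
    list(layer("sequence_input"),
         layer("encoder_dense", out = as.integer(encoder_units)))
  }
  new_arch_spec(
    name = sprintf("rec_spdae_e%d_h%d_%s", encoder_units, bilstm_units,
                   features),
    layers = c(pre, list(
      layer("bilstm", h = as.integer(bilstm_units), return_sequence = FALSE),
      layer("dense", out = as.integer(n_classes)),
      layer("softmax"),
      layer("classification_output"))),
    input_shape = input_shape, n_classes = n_classes)
}

#' Recurrent convolutional network (RCNN)
#'
#' Fourteen layers: sequence input (10 x 240 window treated as an image),
#' sequence folding, two convolution blocks (32 filters of 3 x 3 each,
#' instance normalization, ReLU; the second block uses stride 1 x 4 and
#' dilation 2 x 2, both blocks valid padding), sequence unfolding, flatten,
#' GRU, fully connected, softmax, classification output.
#'
#' @param hidden_units GRU hidden units.
#' @param n_classes Number of classes.
#' @param input_shape Window shape.
#' @return An `arch_spec`.
#' @export
build_rcnn <- function(hidden_units, n_classes = 7L,
                       input_shape = c(10L, 240L)) {
  check_count(hidden_units, "hidden_units")
  new_arch_spec(
    name = sprintf("rcnn_h%d", hidden_units),
    layers = list(
      layer("sequence_input"),
      layer("seq_fold"),
      layer("conv2d", filters = 32L, kernel = c(3L, 3L), stride = c(1L, 1L),
            dilation = c(1L, 1L)),
      layer("instance_norm"),
      layer("relu"),
      layer("conv2d", filters = 32L, kernel = c(3L, 3L), stride = c(1L, 4L),
            dilation = c(2L, 2L)),
      layer("instance_norm"),
      layer("relu"),
      layer("seq_unfold"),
      layer("flatten", keep_time = FALSE),
      layer("gru", h = as.integer(hidden_units), return_sequence = FALSE),
      layer("dense", out = as.integer(n_classes)),
      layer("softmax"),
      layer("classification_output")),
    input_shape = input_shape, n_classes = n_classes)
}

#' DeepConvLSTM benchmark
#'
#' The classic convolutional-recurrent benchmark: four temporal convolution
#' layers (64 filters, 5-sample kernels along the time axis, valid padding)
#' followed by two stacked LSTM layers and a softmax classifier. On a
#' 10 x 240 window the time axis shrinks to 224 and the LSTMs consume
#' 640-dimensional feature vectors (64 filters x 10 channel rows).
#'
#' @param hidden_units LSTM hidden units (default 128).
#' @param n_in Input channels.
#' @param n_classes Number of classes.
#' @param win Window length.
#' @return An `arch_spec`.
#' @export
build_deepconvlstm <- function(hidden_units = 128L, n_in = 10L,
                               n_classes = 7L, win = 240L) {
  check_count(hidden_units, "hidden_units")
  conv <- function() layer("conv2d", filters = 64L, kernel = c(1L, 5L),
                           stride = c(1L, 1L), dilation = c(1L, 1L))
  new_arch_spec(
    name = sprintf("deepconvlstm_h%d", hidden_units),
    layers = list(
      layer("sequence_input"),
      layer("seq_fold"),
      conv(), conv(), conv(), conv(),
      layer("seq_unfold"),
      layer("flatten", keep_time = TRUE),
      layer("lstm", h = as.integer(hidden_units), return_sequence = TRUE),
      layer("lstm", h = as.integer(hidden_units), return_sequence = FALSE),
      layer("dense", out = as.integer(n_classes)),
      layer("softmax"),
      layer("classification_output")),
    input_shape = c(n_in, win), n_classes = n_classes)
}
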