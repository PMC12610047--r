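# Analytic complexity accounting: learnable parameters (LP),
# multiply-accumulate (MAC) and multiply-add (MA) operation counts over one
# inference, memory footprint, and a latency estimate.
#
# Operation-counting convention (pinned by the instrumented oracle in
# ops_oracle): a MAC is one scalar product accumulated into a dot product
# (dense, convolution, and recurrent gate matrix products); MA counts every
# scalar multiplication and every executed addition, including dot-product
# accumulation, bias addition, and elementwise gate/normalization
# arithmetic. Transcendental evaluations (sigmoid, tanh, exp, sqrt) are not
# counted. Divisions count as multiplications.

layer_lp <- function(kind, p, din, cin) {
  switch(kind,
    dense = ,
    encoder_dense = (din + 1L) * p$out,
    bilstm = 2L * (4L * p$h * din + 4L * p$h * p$h + 4L * p$h),
    lstm = 4L * p$h * din + 4L * p$h * p$h + 4L * p$h,
    gru = 3L * p$h * din + 3L * p$h * p$h + 3L * p$h,
    conv2d = (p$kernel[1] * p$kernel[2] * cin + 1L) * p$filters,
    instance_norm = 2L * cin,
    0L)
}

# per-layer (mult, add, mac) triple over one inference pass
layer_ops <- function(kind, p, st_in, st_out) {
  z <- c(mult = 0, add = 0, mac = 0)
  if (kind %in% c("dense", "encoder_dense")) {
    d <- st_in$d; o <- p$out; t_len <- st_in$t
    z <- c(d * o, d * o, d * o) * t_len
  } else if (kind %in% c("lstm", "bilstm")) {
    d <- st_in$d; h <- p$h; t_len <- st_in$t
    dirs <- if (kind == "bilstm") 2 else 1
    per_t <- c(4 * h * (d + h) + 3 * h,   # gate products + cell/output mults
               4 * h * (d + h) + h,       # gate accumulation/bias + cell add
               4 * h * (d + h))
    z <- per_t * t_len * dirs
  } else if (kind == "gru") {
    d <- st_in$d; h <- p$h; t_len <- st_in$t
    per_t <- c(3 * h * (d + h) + 3 * h,
               3 * h * (d + h) + 3 * h,
               3 * h * (d + h))
    z <- per_t * t_len
  } else if (kind == "conv2d") {
    k <- p$kernel[1] * p$kernel[2] * st_in$c
    vol <- st_out$h * st_out$w * st_out$c
    z <- c(k, k, k) * vol
  } else if (kind == "instance_norm") {
    m <- st_in$h * st_in$w
    z <- c((3 * m + 2) * st_in$c, 4 * m * st_in$c, 0)
  } else if (kind == "softmax") {
    o <- st_in$d * st_in$t
    z <- c(o, o, 0)
  }
  stats::setNames(z, c("mult", "add", "mac"))
}

#' Count learnable parameters of an architecture
#'
#' Closed forms per layer: dense `(d + 1) o`; LSTM `4h d + 4h h + 4h` (x2
#' for bidirectional); GRU `3h d + 3h h + 3h`; conv2d
#' `(kh kw cin + 1) F`; instance normalization `2 c`; all other layers 0.
#'
#' @param spec An `arch_spec`.
#' @return Integer total of weights and biases.
#' @export
#' @examples
#' count_learnables(build_bilstm(300))  # 750607
count_learnables <- function(spec) {
  shapes <- infer_shapes(spec)
  total <- 0
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    st_in <- if (i > 1L) shapes$shape[[i - 1L]] else
      shape_seq(spec$input_shape[1], spec$input_shape[2])
    din <- if (st_in$type == "seq") st_in$d else NA_integer_
    cin <- if (st_in$type == "img") st_in$c else NA_integer_
    total <- total + layer_lp(ly$kind, ly$params, din, cin)
  }
  as.integer(total)
}

#' Memory to store the learnable parameters
#'
#' `lp * bytes_per_param / 1048576` (MiB convention, 4 bytes per parameter),
#' rounded to 3 decimals.
#'
#' @param lp Non-negative parameter count.
#' @param bytes_per_param Bytes per parameter (default 4).
#' @return Memory in MB (3 decimals).
#' @export
#' @examples
#' memory_mb(750607)  # 2.863
memory_mb <- function(lp, bytes_per_param = 4) {
  check_non_negative(lp, "lp")
  round(lp * bytes_per_param / 1048576, 3)
}

#' Operation counts over one inference pass
#'
#' `count_mac` totals the scalar products accumulated into dot products
#' (dense `d o`, convolution `kh kw cin` per output element, recurrent gate
#' matrix products per timestep per direction). `count_ma` totals all scalar
#' multiplications and additions, including bias additions and elementwise
#' gate/normalization arithmetic. The convention is pinned by the
#' instrumented reference forward pass [ops_oracle()].
#'
#' @param spec An `arch_spec`.
#' @return Numeric operation count.
#' @export
count_mac <- function(spec) unname(sum_ops(spec)["mac"])

#' @rdname count_mac
#' @export
count_ma <- function(spec) {
  s <- sum_ops(spec)
  unname(s["mult"] + s["add"])
}

sum_ops <- function(spec) {
  shapes <- infer_shapes(spec)
  total <- c(mult = 0, add = 0, mac = 0)
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    st_in <- if (i > 1L) shapes$shape[[i - 1L]] else
      shape_seq(spec$input_shape[1], spec$input_shape[2])
    total <- total + layer_ops(ly$kind, ly$params, st_in, shapes$shape[[i]])
  }
  total
}

#' Inference latency estimate
#'
#' Ratio of the total operation count to the attainable operation rate of
#' the target platform, derated by an empirical efficiency factor (default
#' 0.7) accounting for kernel inefficiency.
#'
#' @param total_ops Total operations of one inference (use [count_ma()]).
#' @param attainable_ops_per_s Peak attainable scalar operations per second.
#' @param efficiency Efficiency factor in (0, 1].
#' @return Estimated seconds per inference.
#' @export
latency_estimate <- function(total_ops, attainable_ops_per_s,
                             efficiency = 0.7) {
  check_non_negative(total_ops, "total_ops")
  check_positive(attainable_ops_per_s, "attainable_ops_per_s")
  if (efficiency <= 0 || efficiency > 1) {
    stop("`efficiency` must be in (0, 1]", call. = FALSE)
  }
  total_ops / (attainable_ops_per_s * efficiency)
}

#' Full complexity report for an architecture
#'
#' @param spec An `arch_spec`.
#' @param attainable_ops_per_s Platform throughput for the latency estimate
#'   (default 28.8e9, indicative of a low-power embedded x86 CPU).
#' @param efficiency Efficiency factor.
#' @return A `complexity_report`: list with totals (`lp`, `mac`, `ma`,
#'   `memory_mb`, `latency_s`) and a `per_layer` tibble.
#' @export
complexity_report <- function(spec, attainable_ops_per_s = 28.8e9,
                              efficiency = 0.7) {
  shapes <- infer_shapes(spec)
  rows <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    st_in <- if (i > 1L) shapes$shape[[i - 1L]] else
      shape_seq(spec$input_shape[1], spec$input_shape[2])
    din <- if (st_in$type == "seq") st_in$d else NA_integer_
    cin <- if (st_in$type == "img") st_in$c else NA_integer_
    ops <- layer_ops(ly$kind, ly$params, st_in, shapes$shape[[i]])
    rows[[i]] <- tibble::tibble(
      layer = i, kind = ly$kind, output = shapes$output[i],
      lp = as.numeric(layer_lp(ly$kind, ly$params, din, cin)),
      mac = ops[["mac"]], ma = ops[["mult"]] + ops[["add"]])
  }
  per_layer <- dplyr::bind_rows(rows)
  lp <- sum(per_layer$lp); ma <- sum(per_layer$ma)
  structure(list(name = spec$name, per_layer = per_layer,
                 lp = as.integer(lp), mac = sum(per_layer$mac), ma = ma,
                 memory_mb = memory_mb(lp),
                 latency_s = latency_estimate(ma, attainable_ops_per_s,
                                              efficiency)),
            class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("<complexity_report> %s\n", x$name))
  cat(sprintf("  LP %s | MAC %s | MA %s | memory %.3f MB | latency %.3g s\n",
              format(x$lp, big.mark = ","), format(x$mac, big.mark = ","),
              format(x$ma, big.mark = ","), x$memory_mb, x$latency_s))
  invisible(x)
}
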