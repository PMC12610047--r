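# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evaluation result into per-class metrics
#' @param x An `eval_result`.
#' @param ... Unused.
#' @return Tibble with one row per class: precision, recall, F1, support.
#' @method tidy eval_result
#' @export
tidy.eval_result <- function(x, ...) x$per_class

#' One-row summary of an evaluation result
#' @param x An `eval_result`.
#' @param ... Unused.
#' @return Tibble with `macro_f1`, `accuracy`, `macro_precision`, `n`.
#' @method glance eval_result
#' @export
glance.eval_result <- function(x, ...) {
  tibble::tibble(macro_f1 = x$macro_f1, accuracy = x$accuracy,
                 macro_precision = x$macro_precision, n = x$n)
}

#' Per-epoch training history of a fitted model
#' @param x A `har_model`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`, `lr`.
#' @method tidy har_model
#' @export
tidy.har_model <- function(x, ...) x$history

#' One-row summary of a fitted model
#' @param x A `har_model`.
#' @param ... Unused.
#' @return Tibble with the architecture name, parameter count, epochs, and
#'   final training loss.
#' @method glance har_model
#' @export
glance.har_model <- function(x, ...) {
  tibble::tibble(arch = x$spec$name, n_params = n_params(x$params),
                 epochs = nrow(x$history),
                 final_loss = x$history$loss[nrow(x$history)])
}

#' Per-layer complexity breakdown
#' @param x A `complexity_report`.
#' @param ... Unused.
#' @return The per-layer tibble (layer, kind, output shape, LP, MAC, MA).
#' @method tidy complexity_report
#' @export
tidy.complexity_report <- function(x, ...) x$per_layer

#' One-row complexity summary
#' @param x A `complexity_report`.
#' @param ... Unused.
#' @return Tibble with `lp`, `mac`, `ma`, `memory_mb`, `latency_s`.
#' @method glance complexity_report
#' @export
glance.complexity_report <- function(x, ...) {
  tibble::tibble(arch = x$name, lp = x$lp, mac = x$mac, ma = x$ma,
                 memory_mb = x$memory_mb, latency_s = x$latency_s)
}

#' Mean and sd of the subject-increment curve
#' @param x A `subject_increment` tibble.
#' @param ... Unused.
#' @return Tibble with per-`n_subjects` mean and sd of macro F1.
#' @method tidy subject_increment
#' @export
tidy.subject_increment <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(x), .data$n_subjects),
                   mean_f1 = mean(.data$macro_f1),
                   sd_f1 = stats::sd(.data$macro_f1), .groups = "drop")
}

#' Confusion-matrix heatmap
#' @param object An `eval_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eval_result
#' @export
autoplot.eval_result <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(as.table(object$cm)))
  names(df) <- c("true", "pred", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev(activity_classes())) +
    ggplot2::labs(x = "predicted", y = "true",
                  title = sprintf("macro F1 = %.3f", object$macro_f1))
}

#' Training-loss curve
#' @param object A `har_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot har_model
#' @export
autoplot.har_model <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = object$spec$name, y = "training loss")
}

#' Hyperparameter-sweep checkerboard
#' @param object A `sweep_result` tibble.
#' @param ... Unused.
#' @return A ggplot object (epochs x hidden units tiles coloured by F1).
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = factor(.data$hidden_units),
                               y = factor(.data$epochs),
                               fill = .data$macro_f1)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$macro_f1)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "hidden units", y = "epochs", fill = "macro F1")
}

#' Subject-increment curve with error bars
#' @param object A `subject_increment` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot subject_increment
#' @export
autoplot.subject_increment <- function(object, ...) {
  s <- tidy.subject_increment(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$n_subjects, y = .data$mean_f1)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_f1 - .data$sd_f1,
      ymax = .data$mean_f1 + .data$sd_f1)) +
    ggplot2::labs(x = "subjects in training pool", y = "macro F1")
}

#' @importFrom rlang .data
NULL
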