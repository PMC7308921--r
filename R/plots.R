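#' Plot an ECG record with its annotations
#'
#' @param object An `ecg_record`.
#' @param seconds How many seconds from the start to show (default 5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecg_record <- function(object, seconds = 5, ...) {
  n <- min(length(object$signal), ceiling(seconds * object$fs))
  df <- tibble(time = (seq_len(n) - 1) / object$fs, signal = object$signal[seq_len(n)])
  ann <- object$annotations |> filter(.data$index <= n)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$signal)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time [s]", y = "amplitude", title = "ECG record") +
    ggplot2::theme_minimal()
  if (nrow(ann) > 0) {
    p <- p + ggplot2::geom_vline(
      data = ann,
      ggplot2::aes(xintercept = (.data$index - 1) / object$fs),
      linetype = "dotted", colour = "red"
    ) +
      ggplot2::geom_text(
        data = ann,
        ggplot2::aes(x = (.data$index - 1) / object$fs, y = max(df$signal),
                     label = .data$label),
        vjust = -0.3, size = 3, colour = "red"
      )
  }
  p
}

#' Convergence curve of an optimizer run
#'
#' Best-so-far fitness (mean cross-validated macro F1, percent) against the
#' objective-evaluation counter.
#'
#' @param object An `optimizer_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.optimizer_run <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$evaluation, y = .data$best_so_far)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "objective evaluations", y = "best fitness so far",
      title = sprintf("%s convergence (best %.2f)", object$method, object$best_fitness)
    ) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heat map
#'
#' @param object A `confusion_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_report <- function(object, ...) {
  m <- object$matrix
  df <- as_tibble(as.data.frame(as.table(m)))
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = log10(.data$count + 1))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(rownames(m))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", guide = "none") +
    ggplot2::labs(x = "predicted", y = "true",
                  title = sprintf("Confusion matrix (macro F1 %.2f%%)",
                                  object$overall$macro_f1)) +
    ggplot2::theme_minimal()
}

#' SOM quantization error over training epochs
#'
#' @param object A `som_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.som_model <- function(object, ...) {
  df <- tibble(epoch = seq_along(object$qe), qe = object$qe)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$qe)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean quantization error",
                  title = sprintf("SOM %dx%d training", object$grid_k, object$grid_k)) +
    ggplot2::theme_minimal()
}

#' Gallery of the eight class templates
#'
#' @param length Template length in samples.
#' @return A ggplot object, one facet per heartbeat class.
#' @export
plot_beat_templates <- function(length = 250) {
  df <- bind_rows(lapply(beat_classes(), function(cls) {
    tpl <- make_class_template(cls, length)
    tibble(class = cls, sample = seq_along(tpl$samples), amplitude = tpl$samples)
  }))
  df$class <- factor(df$class, levels = beat_classes())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~class, nrow = 2) +
    ggplot2::labs(title = "Synthetic beat-morphology templates",
                  x = "sample (360 Hz)", y = "amplitude") +
    ggplot2::theme_minimal()
}
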