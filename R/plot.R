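# ggplot2 visualization of recordings, envelopes and segmentations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a recording waveform
#'
#' @param object A [pcg_recording()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pcg_recording
#' @export
autoplot.pcg_recording <- function(object, ...) {
  df <- data.frame(
    time_s = (seq_along(object$samples) - 1L) / object$rate,
    amplitude = object$samples
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "amplitude",
                  title = object$source_id) +
    ggplot2::theme_minimal()
}

#' Plot a Shannon-energy envelope
#'
#' @param object A `pcg_envelope`.
#' @param ... Unused.
#' @return A ggplot; for a NASE envelope the zero threshold line that
#'   defines lobe boundaries is drawn.
#' @method autoplot pcg_envelope
#' @export
autoplot.pcg_envelope <- function(object, ...) {
  df <- as.data.frame(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = object$kind) +
    ggplot2::theme_minimal()
  if (identical(object$kind, "NASE")) {
    p <- p + ggplot2::geom_hline(yintercept = 0, linetype = 2,
                                 color = "grey40")
  }
  p
}

#' Plot a segmentation, optionally over its waveform
#'
#' @param object A `pcg_segmentation`.
#' @param recording Optional [pcg_recording()] drawn under the intervals.
#' @param ... Unused.
#' @return A ggplot with the labeled intervals as colored bands.
#' @method autoplot pcg_segmentation
#' @export
autoplot.pcg_segmentation <- function(object, recording = NULL, ...) {
  iv <- tidy(object)
  iv$label <- factor(iv$label, levels = SEG_LABELS)
  p <- ggplot2::ggplot()
  if (!is.null(recording)) {
    wf <- data.frame(
      time_s = (seq_along(recording$samples) - 1L) / recording$rate,
      amplitude = recording$samples
    )
    p <- p + ggplot2::geom_line(
      data = wf, ggplot2::aes(.data$time_s, .data$amplitude),
      linewidth = 0.2, color = "grey30"
    )
  }
  p +
    ggplot2::geom_rect(
      data = iv,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf, fill = .data$label),
      alpha = 0.35
    ) +
    ggplot2::scale_fill_manual(values = c(
      S1 = "#d62728", SYSTOLE = "#ffbb78", S2 = "#1f77b4",
      DIASTOLE = "#aec7e8", NOISE = "grey50"
    ), drop = FALSE) +
    ggplot2::labs(x = "time (s)", y = "amplitude", fill = "state") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pcg_segmentation
#' @param segmentation A `pcg_segmentation` (for the wrapper form).
#' @export
plot_segmentation <- function(recording, segmentation, ...) {
  autoplot(segmentation, recording = recording, ...)
}
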