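#' Plot a signal record
#'
#' Channels stacked as facets against time in seconds; detected segments,
#' if supplied, are shaded.
#'
#' @param object A [signal_record].
#' @param segments Optional segment tibble (`start`, `end` in 0-based
#'   samples), e.g. from [segment_record()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.signal_record <- function(object, segments = NULL, ...) {
  fs <- sig_fs(object)
  df <- tibble::as_tibble(as.data.frame(object))
  df$time <- (seq_len(nrow(df)) - 1L) / fs
  long <- tidyr::pivot_longer(df, -"time", names_to = "channel",
                              values_to = "value")
  long$channel <- factor(long$channel, levels = sig_channels(object))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, title = sig_label(object)) +
    ggplot2::theme_minimal()
  if (!is.null(segments) && nrow(segments)) {
    shade <- tibble::tibble(xmin = segments$start / fs,
                            xmax = segments$end / fs)
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "orange"
    )
  }
  p
}
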