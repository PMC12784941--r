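# ggplot2 visualisations for the main result objects.

#' @method autoplot fc_matrix
#' @export
autoplot.fc_matrix <- function(object, value = c("r", "z"), ...) {
  value <- match.arg(value)
  d <- tidy(object)
  d$val <- d[[value]]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$roi1, y = .data$roi2,
                                  fill = .data$val)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = if (value == "r") c(-1, 1) else NULL,
                                  name = value) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("ROI connectivity (%s, n = %d)",
                                  value, object$n_samples)) +
    ggplot2::theme_minimal()
}

#' @method autoplot delta_corr
#' @export
autoplot.delta_corr <- function(object, ...) {
  d <- as_tibble(object)
  d$cell <- paste(d$metric, d$timepoint, sep = " @ ")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell, y = .data$nucleus,
                                  fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(!is.na(.data$significant) &
                                                     .data$significant, "*", "")),
                       size = 5) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "Spearman rho") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Lateralization deltas vs subacute uptake") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Framewise-displacement trace with the selected window
#'
#' @param fd An `fd_trace`.
#' @param window Optional `window_selection` to highlight.
#' @return A ggplot.
#' @export
plot_fd_trace <- function(fd, window = NULL) {
  p <- ggplot2::ggplot(as_tibble(fd), ggplot2::aes(.data$volume, .data$fd)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "volume", y = "FD (mm)") +
    ggplot2::theme_minimal()
  if (!is.null(window))
    p <- p + ggplot2::annotate("rect", xmin = window$start,
                               xmax = window$start + window$length - 1,
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "steelblue")
  p
}
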