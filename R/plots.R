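#' Network plot of direct comparisons
#'
#' Treatments on a circle; edge width proportional to the number of
#' trials providing the direct comparison.
#'
#' @inheritParams validate_trials
#' @return A ggplot object.
#' @export
plot_network <- function(x, codebook = pwv_treatments()) {
  ed <- network_edges(x, codebook)
  trts <- codebook$code[codebook$code %in% unique(x$treatment)]
  k <- length(trts)
  ang <- pi / 2 - 2 * pi * (seq_len(k) - 1) / k
  nodes <- tibble::tibble(treatment = trts, x = cos(ang), y = sin(ang))
  seg <- dplyr::left_join(ed, nodes, by = c(treat1 = "treatment"))
  seg <- dplyr::left_join(seg, nodes, by = c(treat2 = "treatment"),
                          suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend,
                   linewidth = .data$n_studies),
      colour = "grey60") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 4) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = 1.15 * .data$x, y = 1.15 * .data$y,
                                    label = .data$treatment)) +
    ggplot2::scale_linewidth(range = c(0.4, 3), name = "trials") +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void()
}

#' Forest plot of basic effects versus the reference
#'
#' @param object An [nma_fit] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.nma_fit <- function(object, ...) {
  td <- tidy(object)
  td$treatment <- factor(td$treatment, rev(td$treatment))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$treatment)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = paste0("Mean difference vs ", object$reference,
                             " (m/s, 95% CrI)"),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Comparison-adjusted funnel plot
#'
#' @param fd Output of [funnel_data()].
#' @return A ggplot object.
#' @export
plot_funnel <- function(fd) {
  ggplot2::ggplot(fd, ggplot2::aes(x = .data$centered_effect, y = .data$se,
                                   colour = .data$edge)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Study effect centred on comparison mean (m/s)",
                  y = "Standard error") +
    ggplot2::theme_minimal()
}

#' SUCRA bar chart
#'
#' @param rank An `nma_rank` object from [sucra()].
#' @return A ggplot object.
#' @export
plot_sucra <- function(rank) {
  td <- tidy(rank)
  td$treatment <- factor(td$treatment, rev(td$treatment))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$percent, y = .data$treatment)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "SUCRA (%)", y = NULL) +
    ggplot2::theme_minimal()
}
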