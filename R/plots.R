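#' Plot amplification curves
#'
#' Fluorescence versus cycle, one line per well, optionally on a log10
#' fluorescence scale (which renders the exponential phase as a straight
#' line with slope log10 of the efficiency).
#'
#' @param curves Curves tibble (`well`, `cycle`, `fluorescence`).
#' @param log_scale Plot log10 fluorescence (non-positive values dropped).
#' @return A ggplot object.
#' @export
plot_curves <- function(curves, log_scale = FALSE) {
  assert_columns(curves, c("well", "cycle", "fluorescence"), "`curves`")
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$cycle,
                                    y = .data$fluorescence,
                                    group = .data$well,
                                    colour = .data$well)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cycle", y = "fluorescence (a.u.)") +
    ggplot2::theme_minimal()
  if (log_scale) {
    p <- p + ggplot2::scale_y_log10()
  }
  p
}
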