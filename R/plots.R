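#' Plot an identity histogram
#'
#' @param hist Tibble from [identity_distribution()].
#' @return A ggplot object.
#' @export
plot_identity_distribution <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                     y = .data$count)) +
    ggplot2::geom_col(width = (hist$bin_hi - hist$bin_lo)[1] * 0.9,
                      fill = "grey35") +
    ggplot2::labs(x = "identity to parental organellar sequence (%)",
                  y = "segments") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.norg_scan <- function(object, type = c("identity", "lengths"), ...) {
  type <- match.arg(type)
  if (type == "identity") return(plot_identity_distribution(object$identity_histogram))
  ggplot2::ggplot(object$segments,
                  ggplot2::aes(x = .data$length, y = .data$best_identity_pct)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "segment length (bp)", y = "best identity (%)",
                  title = paste(object$species, object$kind)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.norg_pgls <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "predictor", y = "trait",
      subtitle = sprintf("lambda = %.2f, slope = %.3f, R2 = %.3f, p = %.3g",
                         object$lambda, object$slope, object$r_squared,
                         object$p_value)) +
    ggplot2::theme_minimal()
}

#' Paired tolerant-vs-control plot
#'
#' One line per lineage pair, in the style of paired-comparison figures.
#'
#' @param pairs Tibble with `pair_id`, `tolerant`, `control`.
#' @param log10 Plot on a log10 axis?
#' @return A ggplot object.
#' @export
plot_paired <- function(pairs, log10 = TRUE) {
  long <- tidyr::pivot_longer(pairs, c("tolerant", "control"),
                              names_to = "side", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$side, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$pair_id), colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "lineage value") +
    ggplot2::theme_minimal()
  if (log10) p <- p + ggplot2::scale_y_log10()
  p
}
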