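# ggplot2 figures for the main result types.

#' Plot conditional Q-Q curves
#'
#' One curve per conditioning stratum on the -log10 scale with the null
#' diagonal; successive upward deflection with stricter conditioning is the
#' visual signature of cross-trait enrichment.
#'
#' @param curves A `qq_curves` tibble from [conditional_qq()].
#' @return A ggplot object.
#' @export
plot_conditional_qq <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$expected, y = .data$observed,
    colour = factor(.data$stratum_threshold)
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p[1])),
      colour = "p2 stratum"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot qq_curves
#' @export
autoplot.qq_curves <- function(object, ...) plot_conditional_qq(object)

#' Manhattan plot of conjunctional FDR
#'
#' -log10(conjFDR) by genomic position, with the significance threshold as
#' a dashed line and alternating chromosome shading.
#'
#' @param tbl A `conjfdr_tbl` from [compute_conjfdr()].
#' @param threshold Significance threshold to draw (default 0.05).
#' @return A ggplot object.
#' @export
plot_conjfdr_manhattan <- function(tbl, threshold = 0.05) {
  d <- tbl |>
    dplyr::arrange(chrom_rank(.data$chrom), .data$pos) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(.chr_index = dplyr::cur_group_id()) |>
    dplyr::ungroup() |>
    dplyr::mutate(.x = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$.x, y = -log10(.data$conjfdr),
    colour = factor(.data$.chr_index %% 2)
  )) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c("grey30", "steelblue")) +
    ggplot2::labs(x = "Variant (genome order)",
                  y = expression(-log[10](conjFDR))) +
    ggplot2::theme_minimal()
}

#' @method autoplot conjfdr_tbl
#' @export
autoplot.conjfdr_tbl <- function(object, threshold = 0.05, ...) {
  plot_conjfdr_manhattan(object, threshold)
}
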