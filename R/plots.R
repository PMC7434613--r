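#' Conservation scores of annotated variants along the alignment
#'
#' Lollipop-style view of variant parazscores against alignment column,
#' colored by cohort (or by ACMG class when present), mirroring the usual
#' presentation of paralog conservation of case versus population
#' variants.
#'
#' @param annotated An [annotate_variants()] result.
#' @param color Unquoted column to color by (default `cohort`).
#' @return A ggplot object.
#' @export
plot_variant_conservation <- function(annotated, color = cohort) {
  df <- dplyr::filter(as_tibble(annotated), !is.na(.data$column))
  colq <- rlang::enquo(color)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$parazscore)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$column, yend = 0), colour = "grey75"
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = !!colq), size = 2) +
    ggplot2::labs(
      x = "alignment index position",
      y = "parazscore",
      colour = rlang::as_label(colq)
    ) +
    ggplot2::theme_minimal()
}
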