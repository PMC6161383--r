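#' @exportS3Method ggplot2::autoplot
autoplot.ci_graph <- function(object, ...) {
  k <- nrow(object$nodes)
  ang <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
  layout <- tibble::tibble(
    trait = object$nodes$trait, module = object$nodes$module,
    x = cos(ang), y = sin(ang)
  )
  e <- object$edges
  seg <- dplyr::left_join(e, layout[c("trait", "x", "y")],
                          by = c(from = "trait")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(layout[c("trait", "x", "y")], by = c(to = "trait"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y, linewidth = abs(.data$partial_r),
                   colour = .data$strong)
    ) +
    ggplot2::geom_point(data = layout,
                        ggplot2::aes(.data$x, .data$y, shape = .data$module),
                        size = 3) +
    ggplot2::geom_text(data = layout,
                       ggplot2::aes(1.12 * .data$x, 1.12 * .data$y,
                                    label = .data$trait), size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 1.4), guide = "none") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick")) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(
      title = paste0("Conditional-independence graph",
                     if (!is.null(object$group))
                       paste0(" (", object$group, ")")),
      colour = "strong edge"
    )
}

#' Integration versus evolvability across groups
#'
#' Scatter of each group's random-skewers evolvability against its
#' standardized eigenvalue-variance integration index — the visual check of
#' the integration-evolvability tradeoff.
#'
#' @param report A [run_morph_pipeline()] result.
#' @return A ggplot object.
#' @export
plot_integration_evolvability <- function(report) {
  stopifnot(inherits(report, "morph_report"))
  d <- dplyr::inner_join(report$integration, report$evolvability,
                         by = "label")
  ggplot2::ggplot(d, ggplot2::aes(.data$VE_SD, .data$evolvability,
                                  label = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.7, size = 3) +
    ggplot2::labs(x = "integration (VE_SD)",
                  y = "evolvability (mean cosine)") +
    ggplot2::theme_minimal()
}
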