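# ggplot2 methods for the package's result types

#' @export
autoplot.sip_gradient <- function(object, n_taxa = 8, ...) {
  top <- object |>
    dplyr::group_by(.data$taxon_id) |>
    dplyr::summarise(total = sum(.data$mass), .groups = "drop") |>
    dplyr::slice_max(.data$total, n = n_taxa)
  object |>
    dplyr::filter(.data$taxon_id %in% top$taxon_id) |>
    ggplot2::ggplot(ggplot2::aes(.data$density, .data$mass,
                                 colour = .data$taxon_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "buoyant density (g/mL)", y = "DNA mass (a.u.)",
                  colour = "taxon") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.zero_order_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "time (d)", y = "concentration (µmol/L)",
      subtitle = sprintf("%s rate %.3g µmol/L/d (r² = %.3f)",
                         object$mode, object$rate, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.enrichment_calls <- function(object, fold_hi = 10, fold_lo = 2,
                                      dominance = 0.10, ...) {
  d <- dplyr::mutate(object,
                     fold_plot = pmin(.data$fold_vs_both, 1e3)) # cap Inf
  ggplot2::ggplot(d, ggplot2::aes(.data$p_heavy, .data$fold_plot,
                                  colour = .data$branch)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = c(fold_lo, fold_hi), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = dominance, linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "relative abundance in heavy fraction",
                  y = "fold-enrichment vs both controls (capped)",
                  colour = "rule branch") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.prevalence_matrix <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$prevalence, stats::reorder(.data$taxon, .data$prevalence),
                               size = .data$prevalence, colour = .data$retained)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "prevalence across gene sets", y = NULL,
                  size = "prevalence", colour = "retained (>60%)") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-gene RPKM values
#'
#' @param rpkm Output of [rpkm_table()].
#' @return A ggplot object.
#' @export
plot_rpkm <- function(rpkm) {
  ggplot2::ggplot(rpkm, ggplot2::aes(stats::reorder(.data$gene, -.data$rpkm),
                                     .data$rpkm)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "RPKM") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
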